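# shared fixtures and independent oracles

# brute-force motion index: explicit per-pixel loop, kept independent of
# compute_mi's vectorized path
brute_mi_oracle <- function(stack, roi) {
  r <- if (is.character(roi)) stack$rois[[roi]] else roi
  nf <- length(stack$frames)
  out <- numeric(max(nf - 1L, 0L))
  for (t in seq_len(nf - 1L)) {
    acc <- 0
    for (i in r[1]:r[2]) for (j in r[3]:r[4]) {
      acc <- acc + abs(stack$frames[[t + 1L]][i, j] - stack$frames[[t]][i, j])
    }
    out[t] <- acc
  }
  out
}

# random small frame stack with integer intensities
rand_stack <- function(seed, n_frames = 4L, nr = 4L, nc = 4L, maxv = 255L) {
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(i) {
    matrix(sample(0:maxv, nr * nc, replace = TRUE), nr, nc)
  })
  frame_stack(frames, frame_rate_hz = 25,
              rois = list(well = c(1L, nr, 1L, nc)))
}

# brute-force Tanimoto over explicit bit-index sets
tanimoto_setwise <- function(a, b) {
  sa <- which(as.logical(a)); sb <- which(as.logical(b))
  u <- length(union(sa, sb))
  if (u == 0) return(1)
  length(intersect(sa, sb)) / u
}

# minimal schedule shared across scoring tests
minimal_schedule <- function() {
  gen_battery_schedule(assays = character(0))
}
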