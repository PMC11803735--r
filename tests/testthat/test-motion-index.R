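test_that("motion index matches hand-computed frame differences", {
  A <- matrix(0L, 2, 2)
  B <- matrix(c(1L, 3L, 2L, 4L), 2, 2)  # [[1,2],[3,4]] row-wise
  st <- frame_stack(list(A, B), rois = list(w = c(1L, 2L, 1L, 2L)))
  expect_equal(compute_mi(st, "w")$mi, 10)
  # |x| symmetry: swapping the frames leaves MI unchanged
  st_swap <- frame_stack(list(B, A), rois = list(w = c(1L, 2L, 1L, 2L)))
  expect_equal(compute_mi(st_swap, "w")$mi, 10)
  same <- frame_stack(list(B, B, B), rois = list(w = c(1L, 2L, 1L, 2L)))
  expect_equal(compute_mi(same, "w")$mi, c(0, 0))
})

test_that("motion index equals the brute-force per-pixel oracle exactly", {
  for (s in 1:40) {
    st <- rand_stack(s)
    expect_identical(compute_mi(st, "well")$mi, brute_mi_oracle(st, "well"))
  }
})

test_that("MI is invariant to a common pixel permutation and scales linearly", {
  st <- rand_stack(99)
  set.seed(1)
  perm <- sample(16)
  permuted <- lapply(st$frames, function(f) matrix(as.vector(f)[perm], 4, 4))
  stp <- frame_stack(permuted, rois = list(well = c(1L, 4L, 1L, 4L)))
  expect_identical(compute_mi(stp, "well")$mi, compute_mi(st, "well")$mi)
  tripled <- lapply(st$frames, function(f) 3L * f)
  st3 <- frame_stack(tripled, rois = list(well = c(1L, 4L, 1L, 4L)))
  expect_identical(compute_mi(st3, "well")$mi, 3 * compute_mi(st, "well")$mi)
})

test_that("degenerate stacks are handled per contract", {
  one <- frame_stack(list(matrix(0L, 2, 2)), rois = list(w = c(1L, 2L, 1L, 2L)))
  expect_length(compute_mi(one, "w")$mi, 0L)
  expect_error(frame_stack(list(matrix(0L, 2, 2), matrix(0L, 3, 3)),
                           rois = list(w = c(1L, 2L, 1L, 2L))), "same shape")
  expect_error(frame_stack(list(matrix(0L, 2, 2)),
                           rois = list(w = c(1L, 3L, 1L, 2L))), "bounds")
  expect_error(frame_stack(list(matrix(0L, 4, 4)),
                           rois = list(a = c(1L, 2L, 1L, 4L),
                                       b = c(2L, 4L, 1L, 4L))), "overlap")
})

test_that("battery average equals an independent summation oracle", {
  expect_equal(battery_average_mi(rep(7.5, 100)), 7.5)
  expect_equal(battery_average_mi(c(0, 2)), 1)
  set.seed(11)
  x <- runif(4999) * 100
  oracle <- Reduce(`+`, as.list(x)) / length(x)   # sequential pairwise sum
  expect_equal(battery_average_mi(x), oracle, tolerance = 1e-12)
  expect_error(battery_average_mi(numeric(0)), "empty")
})

test_that("lethality call is strict at 1 and monotone under trace lowering", {
  expect_true(lethality_flag(0))
  expect_false(lethality_flag(1))    # strict inequality
  expect_false(lethality_flag(310))  # hyperactive battery average
  set.seed(2)
  for (i in 1:20) {
    x <- runif(50) * 5
    shrink <- x * runif(1)
    if (lethality_flag(mean(x))) expect_true(lethality_flag(mean(shrink)))
  }
})

test_that("dose-response summary computes t-based confidence intervals", {
  s <- dose_response_summary(rep(3.3, 12), rep("a", 12), rep(1, 12))
  expect_equal(s$ci_lo, s$ci_hi)
  expect_equal(s$mean_mi, 3.3)
  s2 <- dose_response_summary(c(0, 2), c("a", "a"), c(1, 1))
  half <- qt(0.975, df = 1) * sd(c(0, 2)) / sqrt(2)
  expect_equal(s2$mean_mi, 1)
  expect_equal(s2$ci_hi, 1 + half)
  expect_equal(s2$ci_lo, 1 - half)
  expect_error(dose_response_summary(numeric(0), character(0), numeric(0)),
               "empty")
})

test_that("hyperactive-then-toxic dosing yields a non-monotone dose curve", {
  sched <- minimal_schedule()
  hyper <- stock_phenotypes()$hyperactive
  doses <- c(0.05, 0.2, 0.39, 3, 12)
  avg <- c(); trt <- c(); conc <- c()
  for (d in doses) for (r in 1:4) {
    tr <- gen_well_trace(sched, hyper, d, seed = stable_hash(1, d, r))
    avg <- c(avg, battery_average_mi(tr)); trt <- c(trt, "hyper"); conc <- c(conc, d)
  }
  s <- dose_response_summary(avg, trt, conc)
  s <- s[order(s$concentration_um), ]
  peak <- which.max(s$mean_mi)
  expect_true(peak > 1 && peak < nrow(s))  # interior maximum
  expect_lt(s$mean_mi[nrow(s)], 1)         # collapse to lethality at high dose
})
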