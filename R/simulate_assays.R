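#' Simulate a voltage-clamp recording of GABA-evoked current block
#'
#' Emulates a two-electrode voltage-clamp paradigm on a GABA-gated chloride
#' channel expressing oocyte held at -60 mV: a baseline (leak) epoch, a
#' GABA-only step, a GABA + test compound co-application, and a washout
#' (GABA-only) epoch after compound removal. Currents are inward (negative).
#' Desensitization/rundown is modeled as a multiplicative amplitude loss of
#' `rundown_frac_per_epoch` between the pre-application measurement and the
#' co-application (and washout) measurements, so the co-application steady
#' amplitude is `i_gaba * (1 - rundown) * (1 - block_frac)` plus noise. An
#' untreated control trace (`block_frac = 0`) therefore measures the
#' rundown directly via its pre/late amplitude ratio.
#'
#' @param i_gaba GABA-evoked steady current magnitude (nA, > 0)
#' @param rundown_frac_per_epoch multiplicative loss per epoch, in `[0, 1)`
#' @param block_frac fraction of current blocked by the compound, `[0, 1]`
#' @param noise_sd current noise (nA)
#' @param leak_na baseline holding (leak) current, negative nA
#' @param seed RNG seed
#' @param sampling_rate_hz samples per second (default 100)
#' @param oocyte_id,treatment annotation
#' @return An `ephys_trace`: list with `time_s`, `current_na`,
#'   `sampling_rate_hz`, `holding_mv`, `epochs` (data.frame `epoch`,
#'   `start_s`, `end_s`), `oocyte_id`, `treatment`.
#' @export
gen_ephys_trace <- function(i_gaba = 500, rundown_frac_per_epoch = 0.1,
                            block_frac = 0, noise_sd = 5, leak_na = -50,
                            seed = 1L, sampling_rate_hz = 100,
                            oocyte_id = "oo1", treatment = "test") {
  stopifnot(block_frac >= 0, block_frac <= 1,
            rundown_frac_per_epoch >= 0, rundown_frac_per_epoch < 1,
            i_gaba > 0)
  epochs <- data.frame(
    epoch = c("baseline", "gaba_only_pre", "coapplication", "gaba_only_post"),
    start_s = c(0, 10, 40, 70), end_s = c(10, 40, 70, 100),
    stringsAsFactors = FALSE)
  r <- rundown_frac_per_epoch
  amp <- c(baseline = 0,
           gaba_only_pre = i_gaba,
           coapplication = i_gaba * (1 - r) * (1 - block_frac),
           gaba_only_post = i_gaba * (1 - r))
  n <- round(max(epochs$end_s) * sampling_rate_hz)
  time_s <- seq_len(n) / sampling_rate_hz
  mu <- rep(leak_na, n)
  for (i in seq_len(nrow(epochs))) {
    idx <- interval_indices(epochs$start_s[i], epochs$end_s[i],
                            sampling_rate_hz, n)
    mu[idx] <- leak_na - amp[[epochs$epoch[i]]]
  }
  set.seed(seed)
  ephys_trace(current_na = mu + stats::rnorm(n, sd = noise_sd),
              sampling_rate_hz = sampling_rate_hz, epochs = epochs,
              oocyte_id = oocyte_id, treatment = treatment)
}

#' Construct an annotated clamp-current trace
#'
#' @param current_na numeric current samples (nA, inward negative)
#' @param sampling_rate_hz sampling rate (> 0)
#' @param epochs data.frame `epoch`, `start_s`, `end_s` — non-overlapping,
#'   ordered labeled intervals
#' @param holding_mv clamp potential (default -60)
#' @param oocyte_id,treatment annotation
#' @export
ephys_trace <- function(current_na, sampling_rate_hz, epochs,
                        holding_mv = -60, oocyte_id = NA_character_,
                        treatment = NA_character_) {
  stopifnot(sampling_rate_hz > 0)
  epochs <- epochs[order(epochs$start_s), , drop = FALSE]
  ne <- nrow(epochs)
  if (ne > 1L && any(epochs$start_s[-1L] < epochs$end_s[-ne] - 1e-9)) {
    stop("epochs overlap")
  }
  structure(list(time_s = seq_along(current_na) / sampling_rate_hz,
                 current_na = as.numeric(current_na),
                 sampling_rate_hz = sampling_rate_hz,
                 holding_mv = holding_mv, epochs = epochs,
                 oocyte_id = oocyte_id, treatment = treatment),
            class = "ephys_trace")
}

#' Simulate a diet-assay mortality table
#'
#' Per-larva deaths are Bernoulli with probability given by a 2-parameter
#' log-logistic curve `p(d) = d^s / (d^s + lc50^s)`; the well-level outcome
#' follows the least-affected-individual rule (a well is dead only if every
#' larva in it is dead).
#'
#' @param doses dose levels in ug compound per well (> 0)
#' @param lc50 per-larva median lethal dose (ug/well, > 0); `Inf` gives an
#'   inert compound
#' @param slope log-logistic slope (> 0)
#' @param n_reps replicate wells per dose (default 12)
#' @param larvae_per_well larvae per well; a single value or a range
#'   `c(min, max)` sampled uniformly (default `c(3, 5)`)
#' @param seed RNG seed
#' @return data.frame: `dose_ug_per_well`, `well_id`, `rep`, `n_larvae`,
#'   `n_dead`, `well_dead`.
#' @export
gen_mortality <- function(doses, lc50, slope = 4, n_reps = 12L,
                          larvae_per_well = c(3L, 5L), seed = 1L) {
  if (any(doses <= 0)) stop("doses must be positive")
  if (!(lc50 > 0)) stop("lc50 must be positive")
  stopifnot(n_reps >= 1L, slope > 0)
  set.seed(seed)
  rows <- list()
  i <- 0L
  for (d in doses) {
    p <- if (is.infinite(lc50)) 0 else d^slope / (d^slope + lc50^slope)
    for (rep in seq_len(n_reps)) {
      i <- i + 1L
      nl <- if (length(larvae_per_well) == 2L) {
        sample(larvae_per_well[1]:larvae_per_well[2], 1L)
      } else as.integer(larvae_per_well)
      outcomes <- stats::rbinom(nl, 1L, p)
      rows[[i]] <- data.frame(dose_ug_per_well = d,
                              well_id = sprintf("D%g_R%02d", d, rep),
                              rep = rep, n_larvae = nl,
                              n_dead = sum(outcomes),
                              well_dead = well_mortality(outcomes == 1L),
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate fingerprints with planted cluster structure
#'
#' Each cluster has a random prototype of bit density `proto_density`;
#' members keep each prototype bit independently with probability
#' `k = 2 s / (1 + s)` (no spurious bits added), which makes the expected
#' within-cluster Tanimoto approximately `k^2 / (2k - k^2) = s` for target
#' similarity `s = within_sim`. Between-cluster similarity concentrates
#' near `proto_density / (2 - proto_density)`, well below typical
#' triage thresholds for the default density.
#'
#' @param n_clusters number of planted clusters
#' @param n_per_cluster members per cluster (scalar or vector)
#' @param n_bits fingerprint length (default 1024)
#' @param within_sim target expected within-cluster Tanimoto, in `(0, 1]`
#' @param proto_density prototype bit density (default 0.08)
#' @param seed RNG seed
#' @return named list of [fingerprint()] (ids `K<k>_M<m>`) with a
#'   `cluster` attribute giving the planted assignment.
#' @export
gen_fingerprints <- function(n_clusters, n_per_cluster, n_bits = 1024L,
                             within_sim = 0.8, proto_density = 0.08,
                             seed = 1L) {
  if (!(within_sim > 0 && within_sim <= 1)) {
    stop("within_sim must be in (0, 1]")
  }
  between <- proto_density / (2 - proto_density)
  if (between >= within_sim) {
    stop("infeasible similarity targets: expected between-cluster similarity ",
         round(between, 3), " is not below within_sim")
  }
  sizes <- rep_len(n_per_cluster, n_clusters)
  keep_p <- 2 * within_sim / (1 + within_sim)
  set.seed(seed)
  fps <- list()
  planted <- integer(0)
  for (k in seq_len(n_clusters)) {
    proto <- stats::runif(n_bits) < proto_density
    for (m in seq_len(sizes[k])) {
      bits <- if (within_sim == 1) proto else {
        proto & (stats::runif(n_bits) < keep_p)
      }
      id <- sprintf("K%02d_M%02d", k, m)
      fps[[id]] <- fingerprint(bits, params = list(n_bits = n_bits,
                                                   type = "synthetic"))
      planted[id] <- k
    }
  }
  attr(fps, "cluster") <- planted
  fps
}
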