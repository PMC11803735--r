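#' Leak-current quality control
#'
#' Oocytes with excessive leak current at the holding potential are
#' excluded. The mean baseline current must not be more negative than the
#' limit; exactly at the limit passes (only "excessive" leak fails).
#'
#' @param trace an [ephys_trace()] with a `baseline` epoch
#' @param limit_na leak limit in nA (default -1000)
#' @return TRUE (pass) or FALSE (fail)
#' @export
leak_qc <- function(trace, limit_na = -1000) {
  ep <- trace$epochs
  if (!"baseline" %in% ep$epoch) stop("trace has no baseline epoch")
  row <- ep[ep$epoch == "baseline", ][1, ]
  idx <- interval_indices(row$start_s, row$end_s, trace$sampling_rate_hz,
                          length(trace$current_na))
  mean(trace$current_na[idx]) >= limit_na
}

#' Steady-state amplitude of an annotated epoch
#'
#' Baseline-subtracted mean current over the final 1 s of the epoch
#' (steady-state convention), returned as the magnitude of the inward
#' current (positive nA).
#'
#' @param trace an [ephys_trace()]
#' @param epoch epoch label (must be annotated and at least 1 s long)
#' @param window_s measurement window at the end of the epoch (default 1 s)
#' @return amplitude in nA (magnitude of inward current)
#' @export
epoch_amplitude <- function(trace, epoch, window_s = 1) {
  ep <- trace$epochs
  row <- ep[ep$epoch == epoch, , drop = FALSE]
  if (nrow(row) != 1L) stop("epoch not annotated: ", epoch)
  if (row$end_s - row$start_s < window_s) {
    stop("epoch ", epoch, " shorter than the ", window_s, " s measurement window")
  }
  n <- length(trace$current_na)
  fr <- trace$sampling_rate_hz
  idx <- interval_indices(row$end_s - window_s, row$end_s, fr, n)
  base_row <- ep[ep$epoch == "baseline", ][1, ]
  bidx <- interval_indices(base_row$end_s - window_s, base_row$end_s, fr, n)
  # inward currents are negative; magnitude of the baseline-subtracted step
  -(mean(trace$current_na[idx]) - mean(trace$current_na[bidx]))
}

#' Rundown fraction from untreated control recordings
#'
#' GABA responses desensitize over repeated/extended application. Untreated
#' control oocytes measure this loss: the rundown fraction is the mean over
#' controls of `1 - late / early`, where `early` is the pre-application
#' GABA amplitude and `late` the GABA amplitude at the position where
#' treated oocytes receive the co-application. Negative values (noise)
#' are floored at 0.
#'
#' @param control_traces list of [ephys_trace()] from untreated oocytes
#' @param early_epoch,late_epoch epoch labels (defaults `gaba_only_pre`,
#'   `gaba_only_post`)
#' @return rundown fraction in `[0, 1)`
#' @export
rundown_fraction <- function(control_traces, early_epoch = "gaba_only_pre",
                             late_epoch = "gaba_only_post") {
  if (inherits(control_traces, "ephys_trace")) {
    control_traces <- list(control_traces)
  }
  if (length(control_traces) < 1L) stop("need at least one control trace")
  fr <- vapply(control_traces, function(tr) {
    early <- epoch_amplitude(tr, early_epoch)
    late <- epoch_amplitude(tr, late_epoch)
    if (abs(early) < .Machine$double.eps^0.5) {
      stop("zero early GABA amplitude in control trace")
    }
    1 - late / early
  }, numeric(1))
  max(0, mean(fr))
}

#' Rundown-adjusted percent block of the GABA-evoked current
#'
#' The remaining current is the co-application amplitude as a fraction of
#' the pre-application GABA amplitude; dividing by `(1 - rundown)` removes
#' the multiplicative amplitude loss measured on untreated controls, and
#' the percent block is `100 * (1 - adjusted remaining)`, clipped to
#' `[0, 100]`. An inactive compound gives 0%, a full channel block 100%.
#'
#' @param trace an [ephys_trace()] with `gaba_only_pre` and `coapplication`
#'   epochs; must pass [leak_qc()]
#' @param rundown rundown fraction from [rundown_fraction()]
#' @param mode `"multiplicative"` (default; divide remaining by 1 - rundown)
#'   or `"subtractive"` (subtract rundown percentage points), for
#'   sensitivity analysis
#' @return percent block in `[0, 100]`
#' @export
percent_block <- function(trace, rundown = 0,
                          mode = c("multiplicative", "subtractive")) {
  mode <- match.arg(mode)
  if (!leak_qc(trace)) stop("trace failed leak QC")
  pre <- epoch_amplitude(trace, "gaba_only_pre")
  co <- epoch_amplitude(trace, "coapplication")
  if (abs(pre) < .Machine$double.eps^0.5) {
    stop("zero pre-coapplication GABA amplitude")
  }
  remaining <- co / pre
  adjusted <- if (mode == "multiplicative") remaining / (1 - rundown)
              else remaining + rundown
  min(100, max(0, 100 * (1 - adjusted)))
}

#' Aggregate per-oocyte percent block for a compound
#'
#' @param blocks numeric vector of per-oocyte percent-block values
#' @param compound_id compound label
#' @param rundown rundown fraction that was applied (recorded)
#' @return `block_result` data.frame: `compound_id`, `n`, `mean_block`,
#'   `sem` (NA when n < 2), `rundown`.
#' @export
aggregate_block <- function(blocks, compound_id = "test", rundown = NA_real_) {
  n <- length(blocks)
  if (n < 3L || n > 6L) {
    warning("percent block aggregated over n = ", n,
            " oocytes; 3-6 expected by design")
  }
  sem <- if (n >= 2L) stats::sd(blocks) / sqrt(n) else NA_real_
  out <- data.frame(compound_id = compound_id, n = n,
                    mean_block = mean(blocks), sem = sem, rundown = rundown,
                    stringsAsFactors = FALSE)
  class(out) <- c("block_result", "data.frame")
  out
}

#' Well mortality by the least-affected-individual rule
#'
#' A well is scored dead only when every larva in it is dead, i.e. when the
#' least-affected individual is dead; a single survivor vetoes.
#'
#' @param per_larva_dead logical vector of per-larva outcomes (TRUE = dead)
#' @return logical well outcome
#' @export
well_mortality <- function(per_larva_dead) {
  if (length(per_larva_dead) == 0L) stop("empty well")
  all(per_larva_dead)
}

#' Maximum-likelihood log-logistic LC50 from well-level mortality
#'
#' Fits a 2-parameter log-logistic dose-mortality model (asymptotes fixed
#' at 0 and 1) to well-level binary outcomes by maximum likelihood. With
#' `least_affected = TRUE` (default) the likelihood respects the
#' least-affected-individual scoring rule: a well of n larvae is dead with
#' probability `F(dose)^n`, so the reported LC50 is the per-larva median
#' lethal dose. With `least_affected = FALSE` the plain well-level logistic
#' is fitted (`P(well dead) = F(dose)`). The confidence interval is a
#' profile-likelihood interval on log(LC50).
#'
#' @param table data.frame with `dose_ug_per_well`, `well_dead` and (when
#'   `least_affected`) `n_larvae`, as produced by [gen_mortality()] or
#'   [read_mortality()]
#' @param least_affected account for larvae count via the all-dead rule
#' @param conf_level CI level (default 0.95)
#' @param abbott apply Abbott background-mortality correction using control
#'   (dose-0 equivalent) wells; off by default (no natural background
#'   mortality in the assay design)
#' @param control_mortality background mortality fraction used when
#'   `abbott = TRUE`
#' @return `lc50_fit` list: `lc50`, `slope`, `loglik`, `ci` (length 2),
#'   `converged`, `model`.
#' @export
fit_lc50 <- function(table, least_affected = TRUE, conf_level = 0.95,
                     abbott = FALSE, control_mortality = 0) {
  d <- table$dose_ug_per_well
  y <- as.numeric(table$well_dead)
  if (length(unique(d)) < 2L) stop("need at least 2 distinct doses")
  if (any(d <= 0)) stop("doses must be positive")
  if (abbott && control_mortality > 0) {
    y <- pmax(0, (y - control_mortality) / (1 - control_mortality))
  }
  nlarv <- if (least_affected) {
    if (is.null(table$n_larvae)) stop("n_larvae required when least_affected = TRUE")
    table$n_larvae
  } else rep(1, length(y))

  no_variation <- all(y == 0) || all(y == 1)
  # complete separation: no dose level with mixed well outcomes pins the
  # slope, which then runs to its bound — no defensible estimate exists
  mixed <- tapply(y, d, function(v) any(v == 0) && any(v == 1))
  separated <- !any(mixed)
  if (no_variation || separated) {
    return(structure(list(lc50 = NA_real_, slope = NA_real_,
                          loglik = NA_real_, ci = c(NA_real_, NA_real_),
                          converged = FALSE,
                          model = if (least_affected) "least_affected" else "well_logistic"),
                     class = "lc50_fit"))
  }

  logd <- log(d)
  slope_bounds <- log(c(0.05, 50))   # numerical guard rails, generous for bioassays
  nll <- function(par) {
    lmu <- par[1]; s <- exp(par[2])
    f <- stats::plogis(s * (logd - lmu))
    p <- pmin(pmax(f^nlarv, 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  start <- c(mean(range(logd)), log(2))
  opt <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = c(min(logd) - 10, slope_bounds[1]),
                      upper = c(max(logd) + 10, slope_bounds[2]),
                      control = list(maxit = 500, factr = 1e4))
  lmu <- opt$par[1]; slope <- exp(opt$par[2])
  converged <- opt$convergence == 0 && is.finite(opt$value)

  # profile-likelihood CI on log(LC50)
  crit <- opt$value + stats::qchisq(conf_level, df = 1) / 2
  pll <- function(l0) {
    o <- stats::optimize(function(ls) nll(c(l0, ls)), interval = slope_bounds)
    o$objective
  }
  bound <- function(dir) {
    step <- 0.1 * dir
    lo <- lmu; hi <- lmu + step
    for (i in 1:200) {
      if (pll(hi) >= crit) break
      lo <- hi; hi <- hi + step
      step <- step * 1.5
      if (abs(hi - lmu) > 20) return(dir * Inf)
    }
    if (pll(hi) < crit) return(dir * Inf)
    stats::uniroot(function(l) pll(l) - crit, lower = min(lo, hi),
                   upper = max(lo, hi), tol = 1e-6)$root
  }
  ci <- if (converged) exp(c(bound(-1), bound(1))) else c(NA_real_, NA_real_)

  structure(list(lc50 = exp(lmu), slope = slope, loglik = -opt$value,
                 ci = ci, converged = converged,
                 model = if (least_affected) "least_affected" else "well_logistic"),
            class = "lc50_fit")
}
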