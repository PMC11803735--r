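#' Strobe score for one well
#'
#' The strobe score is the mean, over six 5 s windows spread across a
#' strobing-light segment, of the maximum MI inside each window, minus the
#' mean MI over a baseline interval immediately preceding the segment.
#' Untreated larvae freeze under strobe, so their window maxima fall below
#' their pre-strobe activity and the score is negative; strobe-driven
#' hyperactivity yields large positive scores.
#'
#' @param trace a [well_trace()] or numeric MI vector
#' @param windows data.frame from [strobe_windows()] (`start_s`, `end_s`)
#' @param baseline_interval `c(start_s, end_s)` of the pre-strobe baseline
#' @param frame_rate_hz needed when `trace` is a bare vector
#' @return scalar score in MI units (may be negative)
#' @export
strobe_score <- function(trace, windows, baseline_interval,
                         frame_rate_hz = NULL) {
  mi <- if (inherits(trace, "well_trace")) trace$mi else trace
  fr <- if (inherits(trace, "well_trace")) trace$frame_rate_hz else frame_rate_hz
  if (is.null(fr)) stop("frame_rate_hz required for bare traces")
  n <- length(mi)
  maxima <- vapply(seq_len(nrow(windows)), function(i) {
    idx <- interval_indices(windows$start_s[i], windows$end_s[i], fr, n)
    if (length(idx) == 0L) stop("empty scoring window after sampling")
    max(mi[idx])
  }, numeric(1))
  bidx <- interval_indices(baseline_interval[1], baseline_interval[2], fr, n)
  if (length(bidx) == 0L) stop("empty baseline interval after sampling")
  mean(maxima) - mean(mi[bidx])
}

#' Default baseline interval for a strobe segment
#'
#' The `baseline_s` seconds immediately preceding the segment (clipped at
#' battery start).
#'
#' @param schedule a [stimulus_schedule()]
#' @param segment_label strobe segment name
#' @param baseline_s baseline length in seconds (default 30)
#' @return `c(start_s, end_s)`
#' @export
baseline_interval_for <- function(schedule, segment_label, baseline_s = 30) {
  row <- schedule[schedule$segment == segment_label, , drop = FALSE]
  if (nrow(row) != 1L) stop("segment not found in schedule: ", segment_label)
  c(max(0, row$start_s - baseline_s), row$start_s)
}

#' Blue and green strobe scores for every well of a plate
#'
#' @param plate a `plate_data` from [gen_plate()], or a list with `traces`
#'   (list of [well_trace()]), `map`, and `schedule`
#' @param blue_segment,green_segment strobe segment labels
#' @param baseline_s pre-strobe baseline length (seconds)
#' @return data.frame: plate, well, compound_id, role, concentration_um,
#'   blue_score, green_score.
#' @export
score_plate <- function(plate, blue_segment = "strobe_blue",
                        green_segment = "strobe_green", baseline_s = 30) {
  sched <- plate$schedule
  wb <- strobe_windows(sched, blue_segment)
  wg <- strobe_windows(sched, green_segment)
  bb <- baseline_interval_for(sched, blue_segment, baseline_s)
  bg <- baseline_interval_for(sched, green_segment, baseline_s)
  map <- plate$map
  if (length(plate$traces) != nrow(map)) {
    stop("traces and plate map describe different well counts")
  }
  # traces are aligned to map rows (gen_plate and run_pipeline guarantee it)
  blue <- vapply(plate$traces, strobe_score, numeric(1), windows = wb,
                 baseline_interval = bb)
  green <- vapply(plate$traces, strobe_score, numeric(1), windows = wg,
                  baseline_interval = bg)
  data.frame(plate = map$plate, well = map$well,
             compound_id = map$compound_id, role = map$role,
             concentration_um = map$concentration_um,
             blue_score = unname(blue), green_score = unname(green),
             stringsAsFactors = FALSE)
}

#' Min-max normalization of scores to [0, 1]
#'
#' Rescales a batch of scores per channel so the batch minimum maps to 0
#' and the maximum to 1; rank order is preserved and the map is idempotent.
#'
#' @param scores numeric vector with at least two distinct values
#' @return numeric vector in `[0, 1]`
#' @export
normalize_scores <- function(scores) {
  rng <- range(scores)
  if (diff(rng) == 0) stop("normalization undefined for constant scores")
  (scores - rng[1]) / diff(rng)
}

#' Solvent-null hit calling
#'
#' A test well is a primary hit when its (blue, raw) strobe score is at
#' least two solvent-score standard deviations above the highest solvent
#' well's score: `threshold = max(solvent) + 2 * sd(solvent)`; ties at the
#' threshold count as hits. The empirical solvent maximum is the screen's
#' control for false positives; no multiple-testing correction is applied.
#'
#' @param test_scores named (compound id) or unnamed numeric vector
#' @param solvent_scores numeric vector of solvent-well scores (>= 2 wells)
#' @param sd_multiplier threshold multiplier (default 2)
#' @return `hit_table` data.frame: `compound_id`, `score`, `solvent_max`,
#'   `solvent_sd`, `threshold`, `is_hit`.
#' @export
call_hits <- function(test_scores, solvent_scores, sd_multiplier = 2) {
  if (length(solvent_scores) < 2L) {
    stop("at least 2 solvent wells are required (SD undefined otherwise)")
  }
  smax <- max(solvent_scores)
  ssd <- stats::sd(solvent_scores)
  thr <- smax + sd_multiplier * ssd
  ids <- names(test_scores)
  if (is.null(ids)) ids <- as.character(seq_along(test_scores))
  out <- data.frame(compound_id = ids, score = unname(test_scores),
                    solvent_max = smax, solvent_sd = ssd, threshold = thr,
                    is_hit = unname(test_scores) >= thr,
                    stringsAsFactors = FALSE)
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Retest dose-response summary of strobe scores
#'
#' Summarizes replicate strobe scores per compound and concentration and
#' flags conditions whose mean score exceeds the vehicle threshold
#' (`max(vehicle) + 2 * sd(vehicle)`), the same rule as primary hit calling.
#'
#' @param scores numeric strobe scores, one per replicate well
#' @param compound,concentration_um condition labels per well
#' @param vehicle_scores scores of vehicle replicate wells (>= 2)
#' @return data.frame: `compound`, `concentration_um`, `n`, `mean_score`,
#'   `distinct` (TRUE when above the vehicle threshold).
#' @export
retest_dose_summary <- function(scores, compound, concentration_um,
                                vehicle_scores) {
  if (length(scores) == 0L) stop("empty condition")
  if (length(vehicle_scores) < 2L) stop("need >= 2 vehicle wells")
  thr <- max(vehicle_scores) + 2 * stats::sd(vehicle_scores)
  key <- interaction(compound, concentration_um, drop = TRUE)
  rows <- lapply(split(seq_along(scores), key), function(idx) {
    data.frame(compound = compound[idx[1]],
               concentration_um = concentration_um[idx[1]],
               n = length(idx), mean_score = mean(scores[idx]),
               distinct = mean(scores[idx]) >= thr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$compound, out$concentration_um), ]
  rownames(out) <- NULL
  attr(out, "vehicle_threshold") <- thr
  out
}
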