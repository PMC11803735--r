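#' Frame stacks and well traces
#'
#' A frame stack is an ordered list of grayscale frames (integer pixel
#' intensities, equal shapes) with a frame rate and a grid of well ROIs
#' (rectangles in pixel coordinates). A well trace is one well's
#' motion-index time series with plate/treatment annotation.
#'
#' @param frames list of integer matrices, all the same shape
#' @param frame_rate_hz acquisition rate
#' @param rois named list of ROIs, each `c(row_min, row_max, col_min,
#'   col_max)` (1-based, inclusive); ROIs must lie within the frame and not
#'   overlap
#' @return A `frame_stack`.
#' @export
frame_stack <- function(frames, frame_rate_hz = 25, rois) {
  stopifnot(length(frames) >= 1L, frame_rate_hz > 0)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must have the same shape")
  }
  nr <- dims[1, 1]; nc <- dims[2, 1]
  occupied <- matrix(FALSE, nr, nc)
  for (nm in names(rois)) {
    r <- rois[[nm]]
    if (r[1] < 1 || r[3] < 1 || r[2] > nr || r[4] > nc || r[1] > r[2] || r[3] > r[4]) {
      stop("ROI out of frame bounds: ", nm)
    }
    cell <- occupied[r[1]:r[2], r[3]:r[4]]
    if (any(cell)) stop("ROIs overlap at: ", nm)
    occupied[r[1]:r[2], r[3]:r[4]] <- TRUE
  }
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz, rois = rois),
            class = "frame_stack")
}

#' @rdname frame_stack
#' @param mi nonnegative numeric motion-index values at frame resolution
#' @param plate,well,treatment annotation
#' @param concentration_um treatment concentration (uM)
#' @export
well_trace <- function(mi, frame_rate_hz = 25, plate = NA_character_,
                       well = NA_character_, treatment = NA_character_,
                       concentration_um = NA_real_) {
  if (any(mi < 0)) stop("MI values must be nonnegative")
  structure(list(mi = as.numeric(mi), frame_rate_hz = frame_rate_hz,
                 plate = plate, well = well, treatment = treatment,
                 concentration_um = concentration_um),
            class = "well_trace")
}

#' Motion index by frame differencing
#'
#' For each consecutive frame pair, the motion index is the sum over ROI
#' pixels of the absolute intensity difference:
#' `MI_t = sum(abs(frame_{t+1} - frame_t))`. Computed in double precision,
#' which is exact for integer intensities (no 8/16-bit wraparound).
#' N frames yield N - 1 MI samples; sample t is timestamped at the later
#' frame of the pair.
#'
#' @param stack a [frame_stack()]
#' @param roi ROI name (from `stack$rois`) or a `c(row_min, row_max,
#'   col_min, col_max)` rectangle
#' @return A [well_trace()]; empty trace for a single-frame stack.
#' @export
compute_mi <- function(stack, roi = names(stack$rois)[1]) {
  stopifnot(inherits(stack, "frame_stack"))
  r <- if (is.character(roi)) {
    if (!roi %in% names(stack$rois)) stop("unknown ROI: ", roi)
    stack$rois[[roi]]
  } else roi
  nf <- length(stack$frames)
  if (nf < 2L) {
    return(well_trace(numeric(0), frame_rate_hz = stack$frame_rate_hz,
                      well = if (is.character(roi)) roi else NA_character_))
  }
  ri <- r[1]:r[2]; ci <- r[3]:r[4]
  prev <- stack$frames[[1L]][ri, ci, drop = FALSE]
  mi <- numeric(nf - 1L)
  for (t in seq_len(nf - 1L)) {
    cur <- stack$frames[[t + 1L]][ri, ci, drop = FALSE]
    mi[t] <- sum(abs(cur - prev))
    prev <- cur
  }
  well_trace(mi, frame_rate_hz = stack$frame_rate_hz,
             well = if (is.character(roi)) roi else NA_character_)
}

#' Battery-average motion index
#'
#' Averages the MI values of the entire battery to a single per-well value,
#' the summary used for lethality calls and dose-response curves.
#'
#' @param trace a [well_trace()] or numeric vector
#' @return scalar mean MI
#' @export
battery_average_mi <- function(trace) {
  mi <- if (inherits(trace, "well_trace")) trace$mi else trace
  if (length(mi) == 0L) stop("empty trace")
  mean(mi)
}

#' Lethality call from the battery average
#'
#' A battery-average MI below 1 is consistent with lethality (complete loss
#' of movement). Strict inequality: exactly 1 is not called lethal.
#'
#' @param avg_mi battery-average MI (>= 0)
#' @return logical
#' @export
lethality_flag <- function(avg_mi) {
  stopifnot(all(avg_mi >= 0))
  avg_mi < 1
}

#' Per-concentration dose-response summary of battery averages
#'
#' Groups wells by treatment and concentration and reports the mean
#' battery-average MI with a Student-t 95% confidence interval (degenerate
#' when n = 1 or the group variance is zero).
#'
#' @param avg_mi numeric battery-average MI per well
#' @param treatment,concentration_um grouping vectors, one entry per well
#' @param conf_level confidence level (default 0.95)
#' @return data.frame: `treatment`, `concentration_um`, `n`, `mean_mi`,
#'   `ci_lo`, `ci_hi`.
#' @export
dose_response_summary <- function(avg_mi, treatment, concentration_um,
                                  conf_level = 0.95) {
  if (length(avg_mi) == 0L) stop("empty group")
  stopifnot(length(treatment) == length(avg_mi),
            length(concentration_um) == length(avg_mi))
  key <- interaction(treatment, concentration_um, drop = TRUE)
  rows <- lapply(split(seq_along(avg_mi), key), function(idx) {
    x <- avg_mi[idx]
    n <- length(x)
    m <- mean(x)
    half <- if (n > 1L && stats::sd(x) > 0) {
      stats::qt(1 - (1 - conf_level) / 2, df = n - 1L) * stats::sd(x) / sqrt(n)
    } else 0
    data.frame(treatment = treatment[idx[1]],
               concentration_um = concentration_um[idx[1]],
               n = n, mean_mi = m, ci_lo = m - half, ci_hi = m + half,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$treatment, out$concentration_um), ]
  rownames(out) <- NULL
  out
}
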