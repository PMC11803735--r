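#' Stimulus schedules for the behavioral battery
#'
#' A stimulus schedule is the timed sequence of assay segments (rest,
#' acoustic, tap, steady light, strobing light) that a plate of larvae is
#' exposed to while motion-index video is recorded. Segments are half-open
#' intervals `[start_s, end_s)` in seconds from battery start.
#'
#' @param segments data.frame with columns `segment`, `stimulus`, `start_s`,
#'   `end_s`, `strobe_hz`, `wavelength_nm`, `irradiance_uw_mm2`.
#' @return A `stimulus_schedule` (a data.frame subclass).
#' @export
stimulus_schedule <- function(segments) {
  stopifnot(is.data.frame(segments))
  req <- c("segment", "stimulus", "start_s", "end_s",
           "strobe_hz", "wavelength_nm", "irradiance_uw_mm2")
  missing_cols <- setdiff(req, names(segments))
  if (length(missing_cols) > 0L) {
    stop("schedule is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  segments <- segments[order(segments$start_s), req]
  if (any(segments$end_s <= segments$start_s)) {
    stop("zero- or negative-duration segments are not allowed")
  }
  if (anyDuplicated(segments$segment)) stop("segment labels must be unique")
  # non-overlap: each segment must start at or after the previous one ends
  n <- nrow(segments)
  if (n > 1L && any(segments$start_s[-1L] < segments$end_s[-n] - 1e-9)) {
    stop("segments overlap")
  }
  rownames(segments) <- NULL
  class(segments) <- c("stimulus_schedule", "data.frame")
  segments
}

#' Generate the default behavioral battery schedule
#'
#' Builds the ~20 min battery: rest, acoustic and tap startle assays, a
#' steady purple-light assay, and one blue plus one green strobing-light
#' assay (120 s each, strobing at 4 Hz). With `assays = character(0)` only
#' the two strobe segments separated by rest remain (the minimal battery).
#'
#' @param config a [sim_config()]; only `frame_rate_hz` is consulted here.
#' @param assays optional assay families to include besides the strobes:
#'   any of `"acoustic"`, `"tap"`, `"light"`.
#' @return A [stimulus_schedule()].
#' @export
gen_battery_schedule <- function(config = sim_config(),
                                 assays = c("acoustic", "tap", "light")) {
  if (length(assays) > 0L) {
    assays <- match.arg(assays, c("acoustic", "tap", "light"), several.ok = TRUE)
  }
  seg <- function(label, stimulus, dur, hz = NA_real_, wl = NA_real_, irr = NA_real_) {
    data.frame(segment = label, stimulus = stimulus, duration_s = dur,
               strobe_hz = hz, wavelength_nm = wl,
               irradiance_uw_mm2 = irr, stringsAsFactors = FALSE)
  }
  parts <- list(seg("rest_1", "rest", 120))
  if ("acoustic" %in% assays) {
    parts <- c(parts, list(seg("acoustic_1", "acoustic", 60), seg("rest_2", "rest", 60)))
  }
  if ("tap" %in% assays) {
    parts <- c(parts, list(seg("tap_1", "tap", 60), seg("rest_3", "rest", 60)))
  }
  if ("light" %in% assays) {
    parts <- c(parts, list(seg("light_purple", "light", 120, wl = 405),
                           seg("rest_4", "rest", 60)))
  }
  if ("acoustic" %in% assays) {
    parts <- c(parts, list(seg("acoustic_2", "acoustic", 60), seg("rest_5", "rest", 60)))
  }
  # blue/green strobes: 4 Hz for 120 s each; nominal wavelength and
  # irradiance recorded as segment metadata
  parts <- c(parts, list(
    seg("strobe_blue", "strobe", 120, hz = 4, wl = 560, irr = 18),
    seg("rest_6", "rest", 60),
    seg("strobe_green", "strobe", 120, hz = 4, wl = 525, irr = 11),
    seg("rest_7", "rest", 60)
  ))
  if ("tap" %in% assays) {
    parts <- c(parts, list(seg("tap_2", "tap", 60), seg("rest_8", "rest", 120)))
  }
  out <- do.call(rbind, parts)
  out$end_s <- cumsum(out$duration_s)
  out$start_s <- out$end_s - out$duration_s
  out$duration_s <- NULL
  stimulus_schedule(out)
}

#' Total duration of a schedule in seconds
#' @param schedule a [stimulus_schedule()]
#' @export
schedule_duration <- function(schedule) {
  max(schedule$end_s)
}

#' Six 5-second scoring windows across a strobe segment
#'
#' Places six non-overlapping 5 s windows evenly across the named segment
#' with maximal spread: window i (i = 0..5) starts at
#' `start + i * (D - 5) / 5` for segment duration D. For D = 120 s the
#' window starts are 0, 23, 46, 69, 92 and 115 s into the segment.
#'
#' @param schedule a [stimulus_schedule()]
#' @param segment_label the segment to score (e.g. `"strobe_blue"`)
#' @param n_windows,window_s window count and width; defaults 6 and 5 s.
#' @return data.frame with columns `window`, `start_s`, `end_s` (absolute
#'   battery time, half-open intervals).
#' @export
strobe_windows <- function(schedule, segment_label, n_windows = 6L, window_s = 5) {
  row <- schedule[schedule$segment == segment_label, , drop = FALSE]
  if (nrow(row) != 1L) stop("segment not found in schedule: ", segment_label)
  D <- row$end_s - row$start_s
  if (D < n_windows * window_s) {
    stop("segment ", segment_label, " is shorter than ", n_windows * window_s,
         " s; cannot place ", n_windows, " windows of ", window_s, " s")
  }
  i <- seq_len(n_windows) - 1L
  starts <- row$start_s + i * (D - window_s) / (n_windows - 1L)
  data.frame(window = seq_len(n_windows), start_s = starts, end_s = starts + window_s)
}

#' Map a time interval to trace sample indices
#'
#' Sample `t` of an MI trace covers the inter-frame interval ending at frame
#' `t + 1`, i.e. sample `t` (1-based) carries timestamp `t / frame_rate_hz`.
#' A half-open interval `[start_s, end_s)` therefore selects samples with
#' `floor(start_s * fr) < t <= floor(end_s * fr)`.
#'
#' @param start_s,end_s interval bounds in seconds
#' @param frame_rate_hz sampling rate
#' @param n_samples trace length, used to clip the upper bound
#' @return integer vector of 1-based sample indices (possibly empty)
#' @export
interval_indices <- function(start_s, end_s, frame_rate_hz, n_samples = Inf) {
  lo <- floor(start_s * frame_rate_hz) + 1L
  hi <- min(floor(end_s * frame_rate_hz), n_samples)
  if (hi < lo) return(integer(0))
  seq.int(lo, hi)
}

#' Write / read a schedule as YAML
#' @param schedule a [stimulus_schedule()]
#' @param path file path
#' @export
write_schedule <- function(schedule, path) {
  yaml::write_yaml(lapply(seq_len(nrow(schedule)), function(i) as.list(schedule[i, ])),
                   path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  rows <- yaml::read_yaml(path)
  df <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(lapply(r, function(x) if (is.null(x)) NA else x),
                  stringsAsFactors = FALSE)
  }))
  for (col in c("strobe_hz", "wavelength_nm", "irradiance_uw_mm2")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  stimulus_schedule(df)
}
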