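#' Simulate one well's motion-index trace
#'
#' Generates an MI trace over the battery. The expected MI inside each
#' segment is the dose-interpolated baseline times the segment gain of the
#' (dose-interpolated) phenotype; truncated-Gaussian noise is added and the
#' trace clipped at zero. At or above the phenotype's toxicity cutoff, or
#' when `params$lethal` is set, the lethal profile (near-zero movement)
#' replaces the phenotype.
#'
#' Dose interpolation: with Hill fraction f = c^h / (c^h + ec^h), every
#' component (baseline, gains, noise) is `vehicle + f * (phenotype -
#' vehicle)`. A phenotype with `ec_um = NULL` is expressed fully at any
#' concentration.
#'
#' @param schedule a [stimulus_schedule()]
#' @param params a [phenotype_params()]
#' @param concentration_um treatment concentration in uM (>= 0)
#' @param seed integer seed for this trace
#' @param frame_rate_hz sampling rate (default 25)
#' @param vehicle the vehicle phenotype used as the interpolation anchor
#' @return A `well_trace` (see [well_trace()]).
#' @export
gen_well_trace <- function(schedule, params, concentration_um = 0, seed = 1L,
                           frame_rate_hz = 25,
                           vehicle = stock_phenotypes()$vehicle) {
  if (nrow(schedule) == 0L) stop("schedule is empty")
  if (concentration_um < 0) stop("negative concentration rejected")
  stopifnot(inherits(params, "phenotype_params"))

  lethal <- params$lethal ||
    (!is.infinite(params$tox_um) && concentration_um >= params$tox_um)
  if (lethal) {
    eff <- list(baseline_mi = 0.2, noise_sd = 0.3, well_cv = 0,
                acoustic_gain = 1, light_gain = 1, strobe_gain = 1)
  } else {
    f <- hill_fraction(concentration_um, params$ec_um, params$hill_slope)
    lerp <- function(field) vehicle[[field]] + f * (params[[field]] - vehicle[[field]])
    eff <- list(baseline_mi = lerp("baseline_mi"), noise_sd = lerp("noise_sd"),
                well_cv = lerp("well_cv"),
                acoustic_gain = lerp("acoustic_gain"),
                light_gain = lerp("light_gain"), strobe_gain = lerp("strobe_gain"))
  }

  n <- round(schedule_duration(schedule) * frame_rate_hz)
  mu <- numeric(n)
  gain_of <- c(rest = 1, acoustic = NA, tap = NA, light = NA, strobe = NA)
  for (i in seq_len(nrow(schedule))) {
    idx <- interval_indices(schedule$start_s[i], schedule$end_s[i],
                            frame_rate_hz, n)
    g <- switch(schedule$stimulus[i],
                rest = 1,
                acoustic = eff$acoustic_gain,
                tap = eff$acoustic_gain,
                light = eff$light_gain,
                strobe = eff$strobe_gain,
                stop("unknown stimulus type: ", schedule$stimulus[i]))
    mu[idx] <- eff$baseline_mi * g
  }
  set.seed(seed)
  # mean-one lognormal well effect: larva batches differ between wells, and
  # a 30000-sample battery average would otherwise have no between-well spread
  if (eff$well_cv > 0) {
    mu <- mu * stats::rlnorm(1, meanlog = -eff$well_cv^2 / 2, sdlog = eff$well_cv)
  }
  mi <- pmax(mu + stats::rnorm(n, sd = eff$noise_sd), 0)
  well_trace(mi, frame_rate_hz = frame_rate_hz,
             concentration_um = concentration_um)
}

#' Default 96-well plate map
#'
#' Column 12 holds 8 vehicle wells; A11/B11 lethal controls; C11/D11
#' hyperactive positive controls; the remaining 84 wells are test compounds
#' screened at a single concentration. A seeded fraction of test compounds
#' is assigned the hyperactive (hit) phenotype; the rest are inactive.
#'
#' @param config a [sim_config()]
#' @param plate_id plate identifier (also prefixes compound ids)
#' @param hit_fraction fraction of test compounds with a real strobe phenotype
#' @param screen_conc_um screening concentration for test wells (uM)
#' @return data.frame with columns `plate`, `well`, `role`, `phenotype`,
#'   `compound_id`, `concentration_um`.
#' @export
default_plate_map <- function(config = sim_config(), plate_id = "P001",
                              hit_fraction = 0.02, screen_conc_um = 0.39) {
  rows <- LETTERS[1:8]
  wells <- as.vector(outer(rows, sprintf("%02d", 1:12), paste0))
  map <- data.frame(plate = plate_id, well = wells, role = "test",
                    phenotype = "inactive",
                    compound_id = paste0(plate_id, "-", wells),
                    concentration_um = screen_conc_um,
                    stringsAsFactors = FALSE)
  veh <- map$well %in% paste0(rows, "12")
  map$role[veh] <- "vehicle"; map$phenotype[veh] <- "vehicle"
  map$compound_id[veh] <- "DMSO"; map$concentration_um[veh] <- 0
  let <- map$well %in% c("A11", "B11")
  map$role[let] <- "lethal_control"; map$phenotype[let] <- "lethal_control"
  map$compound_id[let] <- "lethal_ref"; map$concentration_um[let] <- 100
  pos <- map$well %in% c("C11", "D11")
  map$role[pos] <- "positive_control"; map$phenotype[pos] <- "hyperactive"
  map$compound_id[pos] <- "endosulfan_like"; map$concentration_um[pos] <- 0.3
  test <- map$role == "test"
  is_hit <- vapply(map$compound_id[test], function(id) {
    # the polynomial hash is sequential for neighboring ids; route it through
    # the RNG to get a uniform hit-assignment draw
    set.seed(stable_hash(config$rng_seed, "hitflag", id))
    stats::runif(1) < hit_fraction
  }, logical(1))
  map$phenotype[test][is_hit] <- "hyperactive"
  map
}

#' Simulate a plate of well traces
#'
#' One trace per mapped well. Each well draws from its own RNG stream,
#' seeded by a stable hash of (global seed, plate, well), so well order and
#' plate order never change the result.
#'
#' @param config a [sim_config()]
#' @param plate_id plate identifier
#' @param map plate map; defaults to [default_plate_map()]
#' @param schedule battery schedule; defaults to [gen_battery_schedule()]
#' @return A `plate_data` list: `traces` (named list of [well_trace()]),
#'   `map`, `schedule`, `frame_rate_hz`.
#' @export
gen_plate <- function(config = sim_config(), plate_id = "P001",
                      map = default_plate_map(config, plate_id),
                      schedule = gen_battery_schedule(config, config$assays)) {
  if (any(is.na(map$role)) || any(!nzchar(map$role))) {
    stop("plate map must assign every well a role")
  }
  if (!any(map$role == "vehicle")) {
    stop("plate ", plate_id, " has no vehicle wells")
  }
  unknown <- setdiff(unique(map$phenotype), names(config$phenotypes))
  if (length(unknown) > 0L) {
    stop("plate map uses phenotypes missing from config: ",
         paste(unknown, collapse = ", "))
  }
  vehicle <- config$phenotypes$vehicle
  traces <- lapply(seq_len(nrow(map)), function(i) {
    tr <- gen_well_trace(schedule, config$phenotypes[[map$phenotype[i]]],
                         concentration_um = map$concentration_um[i],
                         seed = stable_hash(config$rng_seed, map$plate[i],
                                            map$well[i]),
                         frame_rate_hz = config$frame_rate_hz,
                         vehicle = vehicle)
    tr$plate <- map$plate[i]; tr$well <- map$well[i]
    tr$treatment <- map$compound_id[i]
    tr
  })
  names(traces) <- map$well
  structure(list(traces = traces, map = map, schedule = schedule,
                 frame_rate_hz = config$frame_rate_hz),
            class = "plate_data")
}

#' Build a frame stack that realizes a target MI trace exactly
#'
#' Constructs integer frames whose per-step sum of absolute pixel
#' differences inside the well ROI equals the (integer) target trace
#' exactly, by raising and lowering a known pixel set by known amounts.
#' This is the oracle fixture for the motion-index formula: by
#' construction, `compute_mi(gen_frames(v), roi)` returns `v`.
#'
#' @param target_trace nonnegative integer vector (or a [well_trace()])
#' @param geometry list with `frame_nrow`, `frame_ncol`, `roi`
#'   (`c(row_min, row_max, col_min, col_max)`), `max_intensity`
#' @param frame_rate_hz stored on the resulting stack
#' @return A [frame_stack()] with `length(target) + 1` frames.
#' @export
gen_frames <- function(target_trace,
                       geometry = list(frame_nrow = 8L, frame_ncol = 8L,
                                       roi = c(1L, 8L, 1L, 8L),
                                       max_intensity = 65535L),
                       frame_rate_hz = 25) {
  v <- if (inherits(target_trace, "well_trace")) target_trace$mi else target_trace
  if (any(v < 0) || any(v != round(v))) {
    stop("target trace must be nonnegative integers")
  }
  v <- as.numeric(round(v))
  roi <- geometry$roi
  maxv <- geometry$max_intensity
  ri <- roi[1]:roi[2]; ci <- roi[3]:roi[4]
  npix <- length(ri) * length(ci)
  frame <- matrix(0, geometry$frame_nrow, geometry$frame_ncol)
  frames <- vector("list", length(v) + 1L)
  frames[[1L]] <- frame
  for (t in seq_along(v)) {
    d <- v[t]
    px <- frame[ri, ci, drop = FALSE]
    # one signed move per pixel per step (so |net deltas| sum exactly to the
    # target); preferred direction alternates so pixels do not ratchet into
    # saturation over long targets
    prefer_up <- t %% 2L == 1L
    for (k in seq_len(npix)) {
      if (d <= 0) break
      cap_up <- maxv - px[k]; cap_dn <- px[k]
      up <- if (prefer_up) cap_up > 0 else cap_dn == 0
      step <- min(d, if (up) cap_up else cap_dn)
      px[k] <- px[k] + if (up) step else -step
      d <- d - step
    }
    if (d > 0) {
      stop("target value ", v[t], " not representable at bit depth / ROI size")
    }
    frame[ri, ci] <- px
    frames[[t + 1L]] <- frame
  }
  frame_stack(frames, frame_rate_hz = frame_rate_hz,
              rois = list(well = roi))
}
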