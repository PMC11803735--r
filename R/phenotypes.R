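#' Phenotype parameters for synthetic well traces
#'
#' A phenotype describes the expected motion-index behavior of larvae in a
#' well under the battery: a resting baseline, multiplicative gains applied
#' during stimulus segments, and trace noise. Dose dependence is encoded by
#' a Hill midpoint/slope pair that interpolates between the vehicle behavior
#' and the full phenotype, plus a toxicity cutoff above which the lethal
#' profile (near-zero movement) replaces the phenotype.
#'
#' @param baseline_mi mean resting motion index (arbitrary MI units, >= 0)
#' @param noise_sd trace noise scale (MI units, >= 0); Gaussian, truncated
#'   at zero because MI is a nonnegative sum of absolute differences
#' @param acoustic_gain multiplicative response during acoustic/tap segments
#' @param light_gain multiplicative response during steady-light segments
#' @param strobe_gain multiplicative activity during strobe segments; < 1
#'   encodes the freezing response of untreated larvae, > 1 the paradoxical
#'   strobe-driven hyperactivity of GABA-antagonist-like compounds
#' @param well_cv coefficient of variation of a mean-one lognormal per-well
#'   baseline multiplier, emulating larva-batch variability between wells;
#'   0 disables it
#' @param lethal if TRUE the well shows near-complete loss of movement
#'   (battery-average MI < 1) regardless of other parameters
#' @param ec_um Hill midpoint (uM) of the dose interpolation between vehicle
#'   and full phenotype; `NULL` means the full phenotype applies at any dose
#' @param hill_slope Hill slope of the dose interpolation
#' @param tox_um concentration (uM) at or above which the lethal profile
#'   applies; `Inf` disables the toxicity switch
#' @return A `phenotype_params` list.
#' @export
phenotype_params <- function(baseline_mi = 30, noise_sd = 5,
                             acoustic_gain = 2, light_gain = 1.5,
                             strobe_gain = 0.05, well_cv = 0, lethal = FALSE,
                             ec_um = NULL, hill_slope = 3, tox_um = Inf) {
  stopifnot(baseline_mi >= 0, noise_sd >= 0, well_cv >= 0,
            acoustic_gain >= 0, light_gain >= 0, strobe_gain >= 0)
  if (!is.null(ec_um)) stopifnot(ec_um > 0, hill_slope > 0)
  structure(list(baseline_mi = baseline_mi, noise_sd = noise_sd,
                 acoustic_gain = acoustic_gain, light_gain = light_gain,
                 strobe_gain = strobe_gain, well_cv = well_cv,
                 lethal = isTRUE(lethal),
                 ec_um = ec_um, hill_slope = hill_slope, tox_um = tox_um),
            class = "phenotype_params")
}

#' Stock phenotypes used throughout the synthetic studies
#'
#' `vehicle`: solvent-treated larvae — moderate baseline, startle responses
#' to acoustic/tap stimuli, and near-complete freezing under strobing light
#' (strobe gain 0.05), which makes the baseline-subtracted strobe score
#' negative. `lethal_control`: anesthetic-killed larvae, flat trace.
#' `hyperactive`: an endosulfan-like GABA-antagonist phenotype — elevated
#' overall activity and strong paradoxical movement under strobe (gain 2.8),
#' active in a sub-micromolar window (Hill midpoint 0.3 uM) and lethal above
#' 1.5 uM, reproducing the rise-then-collapse of the dose-response curve.
#' `inactive`: a test compound with no behavioral effect (vehicle-like).
#'
#' @return named list of [phenotype_params()]
#' @export
stock_phenotypes <- function() {
  list(
    vehicle = phenotype_params(baseline_mi = 30, noise_sd = 5,
                               acoustic_gain = 2, light_gain = 1.5,
                               strobe_gain = 0.05, well_cv = 0.1),
    lethal_control = phenotype_params(baseline_mi = 0.2, noise_sd = 0.3,
                                      acoustic_gain = 1, light_gain = 1,
                                      strobe_gain = 1, lethal = TRUE),
    hyperactive = phenotype_params(baseline_mi = 150, noise_sd = 20,
                                   acoustic_gain = 2, light_gain = 1.8,
                                   strobe_gain = 2.8, well_cv = 0.1,
                                   ec_um = 0.3, hill_slope = 3, tox_um = 1.5),
    inactive = phenotype_params(baseline_mi = 30, noise_sd = 5,
                                acoustic_gain = 2, light_gain = 1.5,
                                strobe_gain = 0.05, well_cv = 0.1)
  )
}

#' Simulation configuration
#'
#' @param n_plates number of plates to simulate
#' @param wells_per_plate wells per plate (default 96)
#' @param larvae_per_well larvae per well (default 8; bookkeeping only —
#'   the unit of analysis is the well)
#' @param frame_rate_hz video frame rate (default 25)
#' @param rng_seed integer seed that fully determines all outputs
#' @param phenotypes named list of [phenotype_params()] keyed by the
#'   `phenotype` column of plate maps
#' @param assays assay families included in the battery besides the strobes
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_plates = 1L, wells_per_plate = 96L,
                       larvae_per_well = 8L, frame_rate_hz = 25,
                       rng_seed = 1L, phenotypes = stock_phenotypes(),
                       assays = c("acoustic", "tap", "light")) {
  stopifnot(frame_rate_hz > 0, wells_per_plate >= 1L, n_plates >= 1L,
            larvae_per_well >= 1L)
  structure(list(n_plates = as.integer(n_plates),
                 wells_per_plate = as.integer(wells_per_plate),
                 larvae_per_well = as.integer(larvae_per_well),
                 frame_rate_hz = frame_rate_hz,
                 rng_seed = as.integer(rng_seed),
                 phenotypes = phenotypes, assays = assays),
            class = "sim_config")
}

#' Stable 31-bit hash for derived RNG streams
#'
#' Polynomial string hash modulo 2^31 - 1, exact in double arithmetic.
#' Used to derive per-well (and per-trace) seeds from the global seed so
#' that generation order never changes results.
#'
#' @param ... components (coerced to character) identifying the stream
#' @return integer in `[0, 2^31 - 2]`
#' @export
stable_hash <- function(...) {
  s <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  p <- 2147483647
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% p
  as.integer(h)
}

# Hill occupancy: fraction of the full phenotype expressed at `conc_um`
hill_fraction <- function(conc_um, ec_um, slope) {
  if (is.null(ec_um)) return(1)
  if (conc_um <= 0) return(0)
  conc_um^slope / (conc_um^slope + ec_um^slope)
}
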