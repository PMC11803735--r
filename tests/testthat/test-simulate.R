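test_that("noiseless traces are piecewise constant at baseline x gain", {
  sched <- gen_battery_schedule()
  p <- phenotype_params(baseline_mi = 10, noise_sd = 0, acoustic_gain = 1,
                        light_gain = 1, strobe_gain = 0)
  tr <- gen_well_trace(sched, p, seed = 1)
  fr <- tr$frame_rate_hz
  for (i in seq_len(nrow(sched))) {
    idx <- interval_indices(sched$start_s[i], sched$end_s[i], fr, length(tr$mi))
    expected <- if (sched$stimulus[i] == "strobe") 0 else 10
    expect_true(all(tr$mi[idx] == expected),
                label = paste("segment", sched$segment[i]))
  }
})

test_that("lethal phenotype yields battery-average MI below 1", {
  sched <- gen_battery_schedule()
  for (s in 1:5) {
    tr <- gen_well_trace(sched, stock_phenotypes()$lethal_control, seed = s)
    expect_lt(battery_average_mi(tr), 1)
  }
})

test_that("traces are seed-deterministic and concentration-validated", {
  sched <- minimal_schedule()
  p <- stock_phenotypes()$hyperactive
  a <- gen_well_trace(sched, p, concentration_um = 0.3, seed = 42)
  b <- gen_well_trace(sched, p, concentration_um = 0.3, seed = 42)
  c <- gen_well_trace(sched, p, concentration_um = 0.3, seed = 43)
  expect_identical(a$mi, b$mi)
  expect_false(identical(a$mi, c$mi))
  expect_error(gen_well_trace(sched, p, concentration_um = -1, seed = 1),
               "negative concentration")
})

test_that("dose interpolation moves the trace from vehicle toward the phenotype", {
  sched <- minimal_schedule()
  veh <- phenotype_params(baseline_mi = 30, noise_sd = 0, strobe_gain = 0.05)
  hyper <- phenotype_params(baseline_mi = 150, noise_sd = 0, strobe_gain = 2.8,
                            ec_um = 0.3, hill_slope = 3, tox_um = Inf)
  avg <- vapply(c(0.01, 0.1, 0.3, 1, 10), function(cc) {
    battery_average_mi(gen_well_trace(sched, hyper, cc, seed = 1, vehicle = veh))
  }, numeric(1))
  expect_true(all(diff(avg) > 0))  # monotone in dose below toxicity
  lo <- battery_average_mi(gen_well_trace(sched, hyper, 0.001, seed = 1, vehicle = veh))
  expect_equal(lo, battery_average_mi(gen_well_trace(sched, veh, 0, seed = 1)),
               tolerance = 0.02)
})

test_that("gen_plate produces one annotated trace per mapped well", {
  cfg <- sim_config(rng_seed = 7, assays = character(0))
  plate <- gen_plate(cfg, "P001")
  expect_equal(length(plate$traces), 96L)
  expect_equal(sum(plate$map$role == "vehicle"), 8L)
  lethal_wells <- plate$map$well[plate$map$role == "lethal_control"]
  for (w in lethal_wells) {
    expect_true(lethality_flag(battery_average_mi(plate$traces[[w]])))
  }
  bad_map <- plate$map
  bad_map$role[bad_map$role == "vehicle"] <- "test"
  expect_error(gen_plate(cfg, "P001", bad_map), "no vehicle wells")
})

test_that("well RNG streams depend on (plate, well), not generation order", {
  cfg <- sim_config(rng_seed = 3, assays = character(0))
  map <- default_plate_map(cfg, "P001")
  plate1 <- gen_plate(cfg, "P001", map)
  rev_map <- map[rev(seq_len(nrow(map))), ]
  plate2 <- gen_plate(cfg, "P001", rev_map)
  expect_identical(plate1$traces[["A01"]]$mi, plate2$traces[["A01"]]$mi)
})

test_that("gen_frames realizes targets exactly and handles edge cases", {
  g <- list(frame_nrow = 4L, frame_ncol = 4L, roi = c(1L, 4L, 1L, 4L),
            max_intensity = 255L)
  z <- gen_frames(c(0, 0, 0), g)
  expect_identical(z$frames[[1]], z$frames[[2]])
  expect_identical(z$frames[[2]], z$frames[[3]])
  one <- gen_frames(10, g)
  expect_equal(sum(abs(one$frames[[2]] - one$frames[[1]])), 10)
  expect_equal(sum(one$frames[[2]] != one$frames[[1]]), 1L)  # single pixel
  expect_error(gen_frames(1e9, g), "not representable")
  expect_error(gen_frames(c(1.5, 2), g), "nonnegative integers")
})

test_that("gen_frames / compute_mi round-trip is exact on random targets", {
  g <- list(frame_nrow = 6L, frame_ncol = 6L, roi = c(2L, 5L, 2L, 5L),
            max_intensity = 255L)
  for (s in 1:25) {
    set.seed(s)
    v <- sample(0:800, 20, replace = TRUE)
    expect_identical(compute_mi(gen_frames(v, g), "well")$mi, as.numeric(v))
  }
})

test_that("vehicle strobe activity is near zero and below hyperactive", {
  sched <- minimal_schedule()
  w <- strobe_windows(sched, "strobe_blue")
  b <- baseline_interval_for(sched, "strobe_blue")
  ph <- stock_phenotypes()
  sv <- vapply(1:20, function(s)
    strobe_score(gen_well_trace(sched, ph$vehicle, 0, seed = s), w, b), numeric(1))
  sh <- vapply(1:20, function(s)
    strobe_score(gen_well_trace(sched, ph$hyperactive, 0.39, seed = 100 + s), w, b),
    numeric(1))
  expect_lt(mean(sv), 0)          # freezing under strobe => negative score
  expect_gt(min(sh), max(sv))     # strict separation at the planted effect
})

test_that("mortality generator respects design and limits", {
  doses <- 2 * 8^((0:6) / 6)   # 7 doses spanning 2-16 ug/well
  tab <- gen_mortality(doses, lc50 = 8.6, slope = 4, n_reps = 12, seed = 1)
  expect_equal(nrow(tab), 84L)
  expect_true(all(tab$n_larvae >= 3 & tab$n_larvae <= 5))
  inert <- gen_mortality(doses, lc50 = Inf, seed = 2)
  expect_true(all(!inert$well_dead))
  hot <- gen_mortality(1000, lc50 = 1, slope = 30, n_reps = 20, seed = 3)
  expect_true(all(hot$well_dead))
  expect_error(gen_mortality(doses, lc50 = -1), "positive")
  expect_error(gen_mortality(c(-2, 4), lc50 = 5), "positive")
})

test_that("per-larva death rate converges to the log-logistic curve", {
  p_true <- function(d) d^4 / (d^4 + 8.6^4)
  tab <- gen_mortality(c(4, 8.6, 14), lc50 = 8.6, slope = 4, n_reps = 400,
                       larvae_per_well = 4, seed = 5)
  for (d in unique(tab$dose_ug_per_well)) {
    sub <- tab[tab$dose_ug_per_well == d, ]
    n <- sum(sub$n_larvae)
    phat <- sum(sub$n_dead) / n
    band <- 4 * sqrt(p_true(d) * (1 - p_true(d)) / n)
    expect_lt(abs(phat - p_true(d)), band)
  }
})

test_that("ephys generator encodes block and rundown in epoch amplitudes", {
  flat <- gen_ephys_trace(500, rundown_frac_per_epoch = 0, block_frac = 0,
                          noise_sd = 0, seed = 1)
  expect_equal(epoch_amplitude(flat, "gaba_only_pre"), 500)
  expect_equal(epoch_amplitude(flat, "coapplication"), 500)
  expect_equal(epoch_amplitude(flat, "gaba_only_post"), 500)
  full <- gen_ephys_trace(500, rundown_frac_per_epoch = 0, block_frac = 1,
                          noise_sd = 0, seed = 1)
  expect_equal(epoch_amplitude(full, "coapplication"), 0)  # back to baseline
  expect_error(gen_ephys_trace(500, block_frac = 2), "block_frac")
})

test_that("planted fingerprint clusters behave as designed", {
  singles <- gen_fingerprints(5, 1, seed = 1)
  a1 <- cluster_compounds(singles, 0.45)
  expect_equal(a1$k, 5L)
  dup <- gen_fingerprints(3, 4, within_sim = 1, seed = 2)
  for (k in 1:3) {
    ids <- names(which(attr(dup, "cluster") == k))
    for (id in ids[-1]) expect_identical(unclass(dup[[id]]), unclass(dup[[ids[1]]]))
  }
  expect_error(gen_fingerprints(3, 4, within_sim = 0.02, proto_density = 0.5),
               "infeasible")
})
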