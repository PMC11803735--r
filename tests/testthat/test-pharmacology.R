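test_that("leak QC fails only truly excessive holding currents", {
  mk <- function(leak) gen_ephys_trace(100, 0, 0, noise_sd = 0, leak_na = leak,
                                       seed = 1)
  expect_true(leak_qc(mk(-50)))
  expect_false(leak_qc(mk(-1500)))
  expect_true(leak_qc(mk(-1000)))  # boundary passes: only "excessive" fails
  bad <- mk(-50); bad$epochs <- bad$epochs[bad$epochs$epoch != "baseline", ]
  expect_error(leak_qc(bad), "baseline")
})

test_that("epoch amplitude is the baseline-subtracted steady-state magnitude", {
  tr <- gen_ephys_trace(100, 0, 0, noise_sd = 0, leak_na = -10, seed = 1)
  expect_equal(epoch_amplitude(tr, "gaba_only_pre"), 100)
  noisy <- gen_ephys_trace(400, 0.1, 0.3, noise_sd = 4, seed = 2)
  planted <- 400 * 0.9 * 0.7
  # mean over 100 samples of sd-4 noise (minus a baseline mean): tight band
  expect_lt(abs(epoch_amplitude(noisy, "coapplication") - planted), 2)
  short <- tr; short$epochs$end_s[2] <- short$epochs$start_s[2] + 0.5
  expect_error(epoch_amplitude(short, "gaba_only_pre"), "shorter")
  expect_error(epoch_amplitude(tr, "nope"), "not annotated")
})

test_that("rundown fraction recovers the planted loss from controls", {
  none <- gen_ephys_trace(300, 0, 0, noise_sd = 0, seed = 1)
  expect_equal(rundown_fraction(list(none)), 0)
  ten <- gen_ephys_trace(300, 0.1, 0, noise_sd = 0, seed = 1)
  expect_equal(rundown_fraction(list(ten)), 0.1)
  # post > pre from noise must floor at zero, never go negative
  set.seed(3)
  fr <- replicate(20, rundown_fraction(list(
    gen_ephys_trace(300, 0, 0, noise_sd = 8, seed = sample.int(1e6, 1)))))
  expect_true(all(fr >= 0))
})

test_that("percent block implements the rundown-adjusted remaining current", {
  null <- gen_ephys_trace(500, 0, 0, noise_sd = 0, seed = 1)
  expect_equal(percent_block(null, 0), 0)
  full <- gen_ephys_trace(500, 0, 1, noise_sd = 0, seed = 1)
  expect_equal(percent_block(full, 0), 100)
  # pre 100 nA, coapplication 40 nA, rundown 0.10 -> 100*(1 - 0.4/0.9)
  hand <- gen_ephys_trace(100, 0.1, 1 - 0.4 / 0.9, noise_sd = 0, seed = 1)
  expect_equal(epoch_amplitude(hand, "coapplication"), 40)
  expect_equal(percent_block(hand, 0.1), 100 * (1 - 0.4 / 0.9), tolerance = 1e-10)
  # subtractive sensitivity mode
  expect_equal(percent_block(hand, 0.1, mode = "subtractive"),
               100 * (1 - (0.4 + 0.1)), tolerance = 1e-10)
})

test_that("percent block is antitone in remaining current and in rundown credit", {
  blocks <- vapply(c(0, 0.2, 0.5, 0.8, 1), function(b) {
    percent_block(gen_ephys_trace(500, 0.1, b, noise_sd = 0, seed = 1), 0.1)
  }, numeric(1))
  expect_true(all(diff(blocks) > 0))
  # crediting more of the amplitude loss to rundown lowers the block
  # attributed to the compound (the 60% -> 55.6% worked example direction)
  tr <- gen_ephys_trace(500, 0.2, 0.4, noise_sd = 0, seed = 1)
  expect_gt(percent_block(tr, 0.05), percent_block(tr, 0.2))
})

test_that("block aggregation reports mean, SEM and design warnings", {
  r <- aggregate_block(c(50, 50, 50), "cmp")
  expect_equal(r$mean_block, 50); expect_equal(r$sem, 0)
  r2 <- suppressWarnings(aggregate_block(c(40, 60), "cmp"))
  expect_equal(r2$mean_block, 50)
  expect_equal(r2$sem, sd(c(40, 60)) / sqrt(2))  # = 10
  expect_warning(aggregate_block(rep(30, 7), "cmp"), "3-6 expected")
  one <- suppressWarnings(aggregate_block(42, "cmp"))
  expect_true(is.na(one$sem))
})

test_that("a well dies only when its least-affected larva is dead", {
  expect_true(well_mortality(c(TRUE, TRUE, TRUE)))
  expect_false(well_mortality(c(TRUE, TRUE, FALSE)))
  expect_error(well_mortality(logical(0)), "empty")
  hot <- gen_mortality(200, lc50 = 8.6, slope = 4, n_reps = 50, seed = 9)
  expect_gt(mean(hot$well_dead), 0.95)
})

test_that("LC50 fit lands on the symmetric-design midpoint", {
  tab <- data.frame(
    dose_ug_per_well = rep(c(1, 10, 100), each = 12),
    well_id = sprintf("w%02d", 1:36), n_larvae = 1L,
    well_dead = c(rep(FALSE, 12), rep(c(TRUE, FALSE), 6), rep(TRUE, 12)))
  f <- fit_lc50(tab)
  expect_true(f$converged)
  expect_equal(f$lc50, 10, tolerance = 1e-4)
  expect_true(f$ci[1] < 10 && f$ci[2] > 10)
})

test_that("degenerate mortality tables flag non-convergence", {
  alive <- data.frame(dose_ug_per_well = rep(c(2, 8), each = 5),
                      well_id = letters[1:10], n_larvae = 4L,
                      well_dead = FALSE)
  f <- fit_lc50(alive)
  expect_false(f$converged)
  expect_true(is.na(f$lc50))
  expect_error(fit_lc50(data.frame(dose_ug_per_well = rep(3, 6),
                                   well_id = letters[1:6], n_larvae = 3L,
                                   well_dead = rep(c(TRUE, FALSE), 3))),
               "2 distinct doses")
})

test_that("LC50 estimation is scale-equivariant", {
  doses <- 2 * 8^((0:6) / 6)
  tab <- gen_mortality(doses, lc50 = 8.6, slope = 4, seed = 21)
  f1 <- fit_lc50(tab)
  tab10 <- tab; tab10$dose_ug_per_well <- tab10$dose_ug_per_well * 10
  f10 <- fit_lc50(tab10)
  expect_equal(f10$lc50 / f1$lc50, 10, tolerance = 1e-6)
  expect_equal(f10$slope, f1$slope, tolerance = 1e-6)
})

test_that("fitted likelihood dominates the generating parameters", {
  doses <- 2 * 8^((0:6) / 6)
  tab <- gen_mortality(doses, lc50 = 8.6, slope = 4, seed = 31)
  f <- fit_lc50(tab)
  ll_true <- sum(dbinom(tab$well_dead,
                        1,
                        pmin(pmax((tab$dose_ug_per_well^4 /
                                   (tab$dose_ug_per_well^4 + 8.6^4))^tab$n_larvae,
                                  1e-12), 1 - 1e-12), log = TRUE))
  expect_gte(f$loglik, ll_true - 1e-6)
})
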