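test_that("strobe score reproduces hand-computed values", {
  sched <- minimal_schedule()
  w <- strobe_windows(sched, "strobe_blue")
  b <- baseline_interval_for(sched, "strobe_blue")
  fr <- 25
  n <- schedule_duration(sched) * fr
  # constant trace: window maxima equal the baseline mean -> 0
  expect_equal(strobe_score(rep(8, n), w, b, frame_rate_hz = fr), 0)
  # zero baseline, a spike of 10 in each window -> 10
  tr <- rep(0, n)
  for (i in 1:6) tr[interval_indices(w$start_s[i], w$end_s[i], fr, n)[3]] <- 10
  expect_equal(strobe_score(tr, w, b, frame_rate_hz = fr), 10)
  # active baseline, frozen strobe windows -> negative score
  tr2 <- rep(0, n)
  tr2[interval_indices(b[1], b[2], fr, n)] <- 30
  expect_equal(strobe_score(tr2, w, b, frame_rate_hz = fr), -30)
})

test_that("strobe score is monotone in window and baseline activity", {
  sched <- minimal_schedule()
  w <- strobe_windows(sched, "strobe_blue")
  b <- baseline_interval_for(sched, "strobe_blue")
  fr <- 25; n <- schedule_duration(sched) * fr
  set.seed(4)
  base <- runif(n) * 20
  s0 <- strobe_score(base, w, b, frame_rate_hz = fr)
  up <- base
  idx <- interval_indices(w$start_s[2], w$end_s[2], fr, n)
  up[idx] <- up[idx] + 5
  expect_gte(strobe_score(up, w, b, frame_rate_hz = fr), s0)
  bl <- base
  bidx <- interval_indices(b[1], b[2], fr, n)
  bl[bidx] <- bl[bidx] + 5
  expect_lte(strobe_score(bl, w, b, frame_rate_hz = fr), s0)
})

test_that("min-max normalization maps batches onto [0, 1] idempotently", {
  expect_equal(normalize_scores(c(0, 5, 10)), c(0, 0.5, 1))
  set.seed(3)
  x <- rnorm(50)
  nx <- normalize_scores(x)
  expect_equal(range(nx), c(0, 1))
  expect_equal(order(nx), order(x))
  expect_equal(normalize_scores(nx), nx)  # idempotence
  expect_error(normalize_scores(rep(2, 5)), "constant")
})

test_that("hit calling applies the max-plus-2-SD solvent rule", {
  solvent <- c(0, 1, 2)  # max 2, sd 1 -> threshold 4
  h <- call_hits(c(a = 3.9, b = 4.0, c = 10), solvent)
  expect_equal(h$threshold[1], 4)
  expect_equal(h$is_hit, c(FALSE, TRUE, TRUE))
  none <- call_hits(c(x = -1, y = 1.5), solvent)
  expect_false(any(none$is_hit))
  degenerate <- call_hits(c(x = 5), c(5, 5, 5))
  expect_equal(degenerate$threshold[1], 5)  # sd 0 -> threshold = solvent max
  expect_true(degenerate$is_hit)            # ties count as hits
  expect_error(call_hits(1, solvent_scores = 3), "2 solvent wells")
})

test_that("retest summary flags planted effects against vehicle", {
  set.seed(6)
  veh <- rnorm(12, 0, 3)
  v <- retest_dose_summary(rnorm(8, 0, 3), rep("vehicle_like", 8),
                           rep(1, 8), veh)
  expect_false(any(v$distinct))
  scores <- c(rnorm(6, 0, 3), rnorm(6, 40, 3))
  s <- retest_dose_summary(scores, rep("hitcmp", 12), rep(c(1, 10), each = 6), veh)
  expect_false(s$distinct[s$concentration_um == 1])
  expect_true(s$distinct[s$concentration_um == 10])
  expect_equal(s$n, c(6, 6))
  expect_error(retest_dose_summary(numeric(0), character(0), numeric(0), veh),
               "empty")
})
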