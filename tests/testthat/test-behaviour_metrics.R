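test_that("inter-tap intervals are strict first differences", {
  expect_equal(inter_tap_intervals(c(0, 1, 2.1)), c(1.0, 1.1))
  expect_equal(inter_tap_intervals(seq(0, 2, by = 0.5)), rep(0.5, 4))
  expect_error(inter_tap_intervals(c(1)), "at least 2")
  expect_error(inter_tap_intervals(c(1, 0.5)), "increasing")
})

test_that("ITI discrepancy and CV match hand computations", {
  expect_equal(iti_discrepancy(rep(1, 10), 1), 1)
  expect_equal(iti_discrepancy(rep(0.3469, 5), 0.3125), 1.11, tolerance = 0.001)
  expect_equal(iti_discrepancy(rep(0.3125 * 1.03, 5), 0.3125), 1.03)
  expect_error(iti_discrepancy(numeric(0), 1), "empty")
  expect_error(iti_discrepancy(1, 0), "isi")

  expect_equal(iti_cv(rep(0.8, 6)), 0)
  expect_equal(iti_cv(c(0.9, 1.0, 1.1)), 10.0)
  expect_equal(iti_cv(c(0.9, 1.0, 1.1) * 3.7), 10.0)  # scale invariance
  expect_error(iti_cv(0.5), "at least 2")
})

test_that("tap phases interpolate between bracketing cues", {
  cues <- 0:10
  expect_equal(tap_phases(3, cues)$phases, 0)
  expect_equal(tap_phases(3.5, cues)$phases, 180)
  expect_equal(tap_phases(3.1, cues)$phases, 36, tolerance = 1e-9)
  # actual bracketing interval is the denominator
  irregular <- c(0, 1, 3)
  expect_equal(tap_phases(2, irregular)$phases, 180)
  ps <- tap_phases(c(-5, 0.25, 20), cues)
  expect_equal(ps$n_dropped, 2)
  expect_error(tap_phases(c(-5, 20), cues), "no taps")
})

test_that("resultant vectors follow the vector sum", {
  expect_equal(resultant_vector(rep(40, 5)),
               list(R = 1, mean_angle = 40), tolerance = 1e-9)
  expect_lt(resultant_vector(c(0, 180))$R, 1e-12)
  r <- resultant_vector(c(0, 90))
  expect_equal(r$R, sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(r$mean_angle, 45)
  expect_error(resultant_vector(numeric(0)), "empty")
})

test_that("circular median minimizes summed circular deviation", {
  expect_equal(circular_median_iqr(c(350, 0, 10))$median_deg, 0)
  expect_equal(circular_median_iqr(c(10, 20, 30, 40, 50))$median_deg, 30)
  # wrap-around cluster: median stays inside the cluster
  set.seed(3)
  a <- wrap_deg(rvonmises_deg(25, 330, 8))
  med <- circular_median_iqr(a)$median_deg
  # brute-force oracle over a 0.1-degree grid
  grid <- seq(0, 359.9, by = 0.1)
  obj <- vapply(grid, function(m) {
    d <- abs(a - m) %% 360
    sum(pmin(d, 360 - d))
  }, numeric(1))
  oracle <- grid[which.min(obj)]
  dd <- abs(med - oracle) %% 360
  expect_lt(min(dd, 360 - dd), 0.5)
  expect_error(circular_median_iqr(c(0, 10)), "at least 3")
})

test_that("IQR brackets the median on the rotated scale", {
  set.seed(4)
  a <- rvonmises_deg(101, 350, 10)
  mi <- circular_median_iqr(a)
  rot <- wrap_deg(a - mi$median_deg + 180)
  q <- unname(quantile(rot, c(0.25, 0.75)))
  expect_equal(wrap_deg(q + mi$median_deg - 180), mi$iqr_deg)
})

test_that("phase-to-asynchrony maps late phases positive, early negative", {
  expect_equal(phase_to_asynchrony_ms(330, 1.0), -83)
  expect_equal(phase_to_asynchrony_ms(0, 0.3125), 0)
  expect_equal(phase_to_asynchrony_ms(134, 1.0), 372)
  expect_equal(phase_to_asynchrony_ms(222, 0.3125), -120)
  expect_error(phase_to_asynchrony_ms(360, 1), "phase")
  # round trip on the 1-ms grid at 1-s ISI
  ms <- -499:500
  ph <- wrap_deg(ms / 1000 * 360)
  expect_equal(phase_to_asynchrony_ms(ph, 1.0), ms)
})

test_that("cross-correlogram peaks at the tap-cue lag", {
  cues <- seq(5, 20, by = 1)
  cc0 <- cross_correlogram(cues, cues, isi = 1)
  expect_equal(cc0$value[which.min(abs(cc0$lag_s))], 1)
  expect_equal(max(cc0$value), 1)
  cc50 <- cross_correlogram(cues + 0.05, cues, isi = 1)
  expect_lt(abs(cc50$lag_s[which.max(cc50$value)] - 0.05), 1 / 256)
  expect_error(cross_correlogram(numeric(0), cues, 1), "empty")
  # uniform random taps: flat correlogram, no dominant bin
  set.seed(5)
  rnd <- sort(runif(400, 5, 20))
  ccr <- cross_correlogram(rnd, cues, isi = 1)
  expect_lt(max(ccr$value), 0.2)
})

test_that("effective tapping rate divides the cue rate by ITI-D", {
  expect_equal(round(effective_rate(3.2, 1.03), 1), 3.1)
  expect_equal(round(effective_rate(3.2, 1.11), 1), 2.9)
  expect_error(effective_rate(3.2, 0), "iti_d")
})

test_that("ITI-CV of simulated taps converges to the configured target", {
  truth <- tap_ground_truth(mean_phase_deg = 0, iti_cv_target = 6)
  sch <- generate_cue_schedule(fast_condition(), 7)  # 357 taps
  sim <- simulate_taps(sch, truth, seed = 8)
  itis <- unlist(lapply(sim$tap_times, inter_tap_intervals))
  expect_gt(length(itis), 300)
  expect_equal(iti_cv(itis), 6, tolerance = 6 * 0.15)
})

test_that("behaviour summary pools retained sequences within condition", {
  sch <- generate_cue_schedule(slow_condition(), 3)
  taps <- lapply(sch$main_beats, function(b) b + 0.05)
  b <- behaviour_summary(taps, sch)
  expect_equal(b$iti_d, 1, tolerance = 1e-9)
  expect_equal(b$iti_cv, 0, tolerance = 1e-9)
  expect_equal(b$mean_phase_deg, 18, tolerance = 1e-6)
  expect_equal(b$n_taps, 48)
})
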