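test_that("the wavelet family spans 12-32 Hz and 3-5 cycles geometrically", {
  fam <- build_wavelet_family(256)
  expect_length(fam$freqs, 11)
  expect_equal(fam$freqs[1], 12)
  expect_equal(fam$freqs[11], 32)
  expect_equal(fam$cycles[1], 3)
  expect_equal(fam$cycles[11], 5)
  expect_equal(fam$freqs[6], sqrt(12 * 32), tolerance = 1e-12)
  expect_equal(fam$cycles[6], sqrt(15), tolerance = 1e-12)
  expect_true(all(diff(log(fam$freqs)) > 0))
  expect_equal(diff(log(fam$freqs)), rep(log(32 / 12) / 10, 10),
               tolerance = 1e-12)
  expect_error(build_wavelet_family(100), "128")
})

test_that("wavelet power localizes tones and vanishes on silence", {
  fs <- 256
  tt <- seq(0, 10, by = 1 / fs)
  mont <- default_montage()[1, , drop = FALSE]
  mk <- function(x) eeg_recording(matrix(x, 1), fs, mont$label,
                                  as.matrix(mont[, c("x", "y", "z")]))
  fam <- build_wavelet_family(fs)

  tf20 <- tf_power(mk(1e-6 * sin(2 * pi * 20 * tt)), fam)
  prof <- apply(tf20$power[1, , 500:2000], 1, mean)
  expect_equal(which.max(prof), which.min(abs(fam$freqs - 20)))
  # stable over time away from edges
  mid <- tf20$power[1, which.max(prof), 500:2000]
  expect_lt(sd(mid) / mean(mid), 0.05)

  tf0 <- tf_power(mk(rep(0, length(tt))), fam)
  expect_lt(max(tf0$power[1, , ]), 1e-25)

  # 13- and 29-Hz tones produce separable maxima
  tf2 <- tf_power(mk(1e-6 * (sin(2 * pi * 13 * tt) + sin(2 * pi * 29 * tt))),
                  fam)
  prof2 <- apply(tf2$power[1, , 500:2000], 1, mean)
  i13 <- which.min(abs(fam$freqs - 13)); i29 <- which.min(abs(fam$freqs - 29))
  trough <- min(prof2[(i13 + 1):(i29 - 1)])
  expect_gt(prof2[i13], 2 * trough)
  expect_gt(prof2[i29], 2 * trough)
})

test_that("white-noise power is roughly flat across the family", {
  set.seed(41)
  fs <- 256
  mont <- default_montage()[1, , drop = FALSE]
  rec <- eeg_recording(matrix(rnorm(20 * fs), 1) * 1e-6, fs, mont$label,
                       as.matrix(mont[, c("x", "y", "z")]))
  fam <- build_wavelet_family(fs)
  tfp <- tf_power(rec, fam)
  prof <- apply(tfp$power[1, , tfp$valid[11, ]], 1, mean)
  # unit-energy kernels: flat expectation; allow generous sampling spread
  expect_lt(max(prof) / min(prof), 1.6)
})

test_that("baseline segmentation yields 26 half-second epochs from 15 s", {
  defs <- baseline_epoch_defs(256, c(0, 15))
  expect_equal(nrow(defs), 26)
  expect_equal(defs$i1 - defs$i0 + 1, rep(128, 26))
  expect_error(baseline_epoch_defs(256, c(0, 2)), "3 s")
})

test_that("baseline spectra are stable across split halves", {
  sch <- generate_cue_schedule(slow_condition(), 1)
  sim <- simulate_taps(sch, tap_ground_truth(mean_phase_deg = 0, kappa = Inf),
                       seed = 42)
  rec <- simulate_eeg(sch, sim$tap_times, beta_effect_spec(), seed = 43)
  tfp <- tf_power(rec)
  defs <- baseline_epoch_defs(rec$sample_rate, sch$baseline_window)
  b1 <- segment_baseline(tfp, defs, keep = seq_len(26) <= 13)
  b2 <- segment_baseline(tfp, defs, keep = seq_len(26) > 13)
  # per-channel band means: each half is only 6.5 s, so allow the sampling
  # spread of a ~30-sample power estimate; the overall mean must be tight
  ratio_db <- 10 * log10(rowMeans(b1) / rowMeans(b2))
  expect_lt(max(abs(ratio_db)), 1.5)
  expect_lt(abs(mean(ratio_db)), 0.3)
  expect_error(segment_baseline(tfp, defs, keep = rep(FALSE, 26)),
               "rejected")
})

test_that("tap epochs span twice the ISI and drop edge taps", {
  expect_equal(with(tap_epoch_defs(256, 5, 1), i1 - i0 + 1), 513)
  expect_equal(with(tap_epoch_defs(256, 5, 0.3125), (i1 - i0 + 1) / 256),
               0.625, tolerance = 1e-2)
  sch <- generate_cue_schedule(slow_condition(), 1)
  sim <- simulate_taps(sch, tap_ground_truth(mean_phase_deg = 0, kappa = Inf),
                       seed = 44)
  rec <- simulate_eeg(sch, sim$tap_times, beta_effect_spec(), seed = 45)
  tfp <- tf_power(rec)
  # a fake tap at the very start of the recording must be dropped
  ep <- epoch_around_taps(tfp, c(0.05, unlist(sim$tap_times)), 1)
  expect_equal(ep$n_dropped, 1)
  expect_equal(dim(ep$power)[1], 16)
  expect_equal(range(ep$rel_times), c(-1, 1))
})

test_that("artefact rules reject spikes but spare homogeneous data", {
  set.seed(46)
  mont <- default_montage()[1:4, ]
  fs <- 256
  n <- 40 * fs
  x <- matrix(rnorm(4 * n, sd = 10e-6), 4)
  rec <- eeg_recording(x, fs, mont$label, as.matrix(mont[, c("x", "y", "z")]))
  rec <- inject_spikes(rec, times = 20.1, amplitude_v = 150e-6, channel = 2)
  tfp <- tf_power(rec)
  defs <- data.frame(i0 = (0:39) * fs + 1, i1 = (1:40) * fs,
                     type = "baseline")
  keep <- reject_artefact_epochs(rec, tfp, defs)
  spike_epoch <- which(defs$i0 <= 20.1 * fs & defs$i1 >= 20.1 * fs)
  expect_false(keep[spike_epoch])
  # union of four independent per-channel 2-SD tails expects ~9% rejected
  expect_lt(mean(!keep), 0.20)

  # identical epochs: SD of every statistic is zero, nothing is rejected
  xc <- matrix(rep(sin(2 * pi * 20 * (1:fs) / fs), 40), 4, n, byrow = TRUE) * 1e-6
  recc <- eeg_recording(xc, fs, mont$label, as.matrix(mont[, c("x", "y", "z")]))
  tfc <- tf_power(recc)
  keepc <- reject_artefact_epochs(recc, tfc, defs)
  expect_true(all(keepc))
})

test_that("decibel normalization follows 10 log10(power/baseline)", {
  ep <- structure(list(
    power = array(2, c(3, 2, 4, 5)),
    rel_times = seq(-0.5, 0.5, length.out = 5),
    freqs = c(12, 18, 25, 30), fs = 256, channels = c("C3", "C4")
  ), class = "tf_epochs")
  base <- matrix(1, 2, 4)
  dbe <- db_normalize(ep, base)
  expect_equal(max(abs(dbe$power - 10 * log10(2))), 0, tolerance = 1e-12)
  expect_equal(db_normalize(ep, base * 2)$power[1, 1, 1, 1], 0)
  expect_equal(db_normalize(ep, base * 20)$power[1, 1, 1, 1], -10)
  expect_error(db_normalize(ep, base * 0), "strictly positive")
})

test_that("window averaging splits one ISI 30/70 around the tap", {
  w1 <- analysis_windows(1)
  expect_equal(w1$around, c(-0.3, 0.2))
  expect_equal(w1$after, c(0.2, 0.7))
  w3 <- analysis_windows(0.3125)
  expect_equal(w3$around, c(-0.09375, 0.0625))
  expect_equal(w3$after, c(0.0625, 0.21875))

  # constant 1-dB map averages to 1 dB in both windows
  nt <- 101
  ep <- structure(list(
    power = array(1, c(6, 2, 11, nt)),
    rel_times = seq(-1, 1, length.out = nt),
    freqs = build_wavelet_family(256)$freqs, fs = 256,
    channels = c("C3", "C4")
  ), class = "tf_epochs")
  wa <- window_average(ep, 1)
  expect_equal(wa$value_db, rep(1, 4), tolerance = 1e-12)
  # the 32-Hz wavelet is excluded from the beta-band average
  ep2 <- ep
  ep2$power[, , 11, ] <- 1000
  expect_equal(window_average(ep2, 1)$value_db, rep(1, 4), tolerance = 1e-12)
})

test_that("a null planted envelope reads out near 0 dB everywhere", {
  wa <- measure_planted_db(slow_condition(), around_db = 0, after_db = 0,
                           seed = 47)
  # per-channel values carry the finite-baseline sampling noise (~0.3 dB
  # SD); the across-channel mean must be close to the planted 0 dB
  expect_lt(abs(mean(wa$value_db[wa$window == "around"])), 0.15)
  expect_lt(abs(mean(wa$value_db[wa$window == "after"])), 0.15)
  expect_lt(max(abs(wa$value_db)), 1)
})
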