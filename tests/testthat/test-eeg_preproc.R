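test_that("EEG band-pass preserves the passband and removes DC and 50 Hz", {
  fs <- 1024
  tt <- seq(0, 8, by = 1 / fs)
  mont <- default_montage()[1:2, ]
  mk <- function(x) eeg_recording(rbind(x, x) * 1e-6, fs, mont$label,
                                  as.matrix(mont[, c("x", "y", "z")]))
  mid <- function(x) x[(length(x) / 4):(3 * length(x) / 4)]

  r20 <- bandpass_eeg(mk(sin(2 * pi * 20 * tt)))
  expect_equal(r20$sample_rate, 256)
  expect_equal(max(abs(mid(r20$data[1, ]))), 1e-6, tolerance = 0.05)

  r50 <- bandpass_eeg(mk(sin(2 * pi * 50 * tt)))
  expect_lt(max(abs(mid(r50$data[1, ]))), 0.5e-6)

  rdc <- bandpass_eeg(mk(rep(3, length(tt))))
  expect_lt(max(abs(mid(rdc$data[1, ]))), 0.05e-6)

  expect_error(bandpass_eeg(mk(tt), hi = 600), "sample rate")
})

test_that("channel QC flags extremes and spares physiological amplitudes", {
  mont <- default_montage()[1:3, ]
  sq <- rep(c(100e-6, -100e-6), 500)           # +-100 uV square wave
  flat <- rnorm(1000, sd = 0.1e-6)             # ~0.08 uV mean abs
  good <- rnorm(1000, sd = 12.5e-6)            # ~10 uV mean abs
  rec <- eeg_recording(rbind(sq, flat, good), 256, mont$label,
                       as.matrix(mont[, c("x", "y", "z")]))
  flags <- flag_bad_channels(rec)
  expect_equal(unname(flags), c(TRUE, TRUE, FALSE))
})

test_that("spherical-spline interpolation reconstructs smooth fields", {
  mont <- default_montage()
  pos <- as.matrix(mont[, c("x", "y", "z")])
  flags <- rep(FALSE, 30); flags[match("FC1", mont$label)] <- TRUE

  const <- eeg_recording(matrix(4e-6, 30, 4), 256, mont$label, pos)
  ic <- interpolate_channels(const, flags)
  expect_equal(ic$data[flags, ], rep(4e-6, 4), tolerance = 1e-12)

  # low-order harmonic field: error well under 5% of the field's spread
  fld <- (pos[, 3] + 0.5 * pos[, 1]) * 1e-5
  harm <- eeg_recording(matrix(fld, 30, 2), 256, mont$label, pos)
  ih <- interpolate_channels(harm, flags)
  expect_lt(abs(ih$data[flags, 1] - fld[flags]) / sd(fld), 0.05)

  expect_error(interpolate_channels(harm, rep(TRUE, 30)), "too many")
})

test_that("average reference zeroes the channel sum and common offsets", {
  mont <- default_montage()[1:4, ]
  pos <- as.matrix(mont[, c("x", "y", "z")])
  x <- matrix(rnorm(4 * 100), 4) * 1e-6
  rec <- eeg_recording(x, 256, mont$label, pos)
  ra <- rereference_average(rec)
  expect_lt(max(abs(colSums(ra$data))), 1e-18)
  # a pure common offset is removed entirely
  off <- rereference_average(eeg_recording(x + 7e-6, 256, mont$label, pos))
  expect_equal(off$data, ra$data, tolerance = 1e-12)
  # two antisymmetric channels are unchanged
  anti <- eeg_recording(rbind(x[1, ], -x[1, ]), 256, mont$label[1:2], pos[1:2, ])
  expect_equal(rereference_average(anti)$data, anti$data)
})

test_that("the surface Laplacian is zero on constants and sharpens bumps", {
  mont <- default_montage()
  pos <- as.matrix(mont[, c("x", "y", "z")])
  const <- eeg_recording(matrix(2e-6, 30, 3), 256, mont$label, pos)
  lc <- surface_laplacian(const)
  expect_lt(max(abs(lc$data)), 1e-12)
  expect_equal(lc$unit, "V/m2")

  # degree-1 spherical harmonic is an eigenfunction: output proportional
  fld <- pos[, 3] * 1e-5
  lh <- surface_laplacian(eeg_recording(matrix(fld, 30, 1), 256,
                                        mont$label, pos))
  fit <- lm(lh$data[, 1] ~ fld)
  expect_gt(summary(fit)$r.squared, 0.99)

  # focal bump comes out spatially sharper (fewer above-half-max channels)
  c3 <- pos[match("C3", mont$label), ]
  ang <- acos(pmin(pmax(pos %*% c3, -1), 1))
  bump <- exp(-ang^2 / (2 * 0.4^2)) * 1e-5
  lb <- surface_laplacian(eeg_recording(matrix(bump, 30, 1), 256,
                                        mont$label, pos))
  expect_lt(sum(lb$data[, 1] > 0.5 * max(lb$data[, 1])),
            sum(bump > 0.5 * max(bump)))

  # reference invariance: adding a common signal changes nothing
  shift <- eeg_recording(matrix(bump + 3e-6, 30, 1), 256, mont$label, pos)
  ls <- surface_laplacian(shift)
  expect_lt(max(abs(ls$data - lb$data)) / sd(lb$data), 1e-6)

  small <- eeg_recording(matrix(0, 10, 3), 256, mont$label[1:10], pos[1:10, ])
  expect_error(surface_laplacian(small), "16")
})

test_that("preprocessing is linear in the input amplitude", {
  mont <- default_montage()
  pos <- as.matrix(mont[, c("x", "y", "z")])
  set.seed(31)
  x <- matrix(rnorm(30 * 2048), 30) * 1e-6
  rec <- eeg_recording(x, 1024, mont$label, pos)
  rec3 <- eeg_recording(3 * x, 1024, mont$label, pos)
  p1 <- surface_laplacian(rereference_average(bandpass_eeg(rec)))
  p3 <- surface_laplacian(rereference_average(bandpass_eeg(rec3)))
  expect_equal(p3$data, 3 * p1$data, tolerance = 1e-9)
})

test_that("montage JSON and recording bundles round-trip", {
  mont <- default_montage()
  expect_equal(nrow(mont), 30)
  expect_true(all(abs(rowSums(as.matrix(mont[, c("x", "y", "z")])^2) - 1) < 1e-9))
  expect_true(all(c("Fp1", "F7", "Oz") %in% attr(mont, "blacklist")))
  p <- tempfile(fileext = ".json")
  write_montage_json(mont, p)
  back <- read_montage_json(p)
  expect_equal(back$label, mont$label)
  expect_equal(back$x, mont$x, tolerance = 1e-12)
  expect_equal(attr(back, "blacklist"), attr(mont, "blacklist"))

  rec <- eeg_recording(matrix(rnorm(60), 30) * 1e-6, 256, mont$label,
                       as.matrix(mont[, c("x", "y", "z")]),
                       events = data.frame(onset_s = 1, event_type = "main"))
  pref <- tempfile()
  write_recording_bundle(rec, pref)
  rback <- read_recording_bundle(pref)
  expect_equal(rback$data, rec$data, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rback$sample_rate, 256)
  expect_equal(rback$events$event_type, "main")
})
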