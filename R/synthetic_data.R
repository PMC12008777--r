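# Ground-truthed synthetic data: cue-locked tap trains with von Mises phase
# jitter, 3-axis accelerometer transients, and multichannel EEG built from a
# 1/f background plus a beta-band component whose amplitude envelope is
# modulated in tap-locked windows by known decibel amounts. Every stage of
# the analysis can be exercised closed-loop against these known truths.

#' Tap ground-truth parameters
#'
#' @param mean_phase_deg Circular mean of the tap phase relative to the cue
#'   (0 = on the cue, 330 = 30/360 of a cycle early).
#' @param kappa von Mises concentration of the phase (Inf = no jitter).
#' @param miss_prob Probability that a cue spawns no tap (in [0, 1)).
#' @param iti_cv_target Optional target inter-tap-interval CV in percent;
#'   when given, `kappa` is derived so independent per-tap phase jitter
#'   yields approximately this CV.
#' @return A list of class `tap_ground_truth`.
#' @export
tap_ground_truth <- function(mean_phase_deg = 350, kappa = 50,
                             miss_prob = 0, iti_cv_target = NULL) {
  if (miss_prob < 0 || miss_prob >= 1) stop("miss_prob must be in [0, 1)")
  if (!is.null(iti_cv_target)) {
    if (iti_cv_target <= 0) stop("iti_cv_target must be > 0")
    # tap-time jitter sd = sigma_phase/(2*pi) * isi; independent jitter makes
    # interval sd sqrt(2) larger; CV% = 100*sqrt(2)*sigma_phase/(2*pi)
    sigma <- iti_cv_target / 100 * 2 * pi / sqrt(2)
    kappa <- vm_A1inv(exp(-sigma^2 / 2))
  }
  if (!is.infinite(kappa) && kappa <= 0) stop("concentration must be > 0")
  structure(list(mean_phase_deg = wrap_deg(mean_phase_deg), kappa = kappa,
                 miss_prob = miss_prob, iti_cv_target = iti_cv_target),
            class = "tap_ground_truth")
}

#' Accelerometer trace container
#' @param samples 3 x N matrix (axes x samples).
#' @param sample_rate Hz.
#' @return An object of class `accel_trace`.
#' @export
accel_trace <- function(samples, sample_rate) {
  samples <- as.matrix(samples)
  if (nrow(samples) != 3) stop("accelerometer trace needs 3 axes")
  if (ncol(samples) == 0) stop("empty trace")
  structure(list(samples = samples, sample_rate = sample_rate),
            class = "accel_trace")
}

# signed cycle fraction in (-0.5, 0.5] for a phase in degrees
phase_to_frac <- function(phase_deg) {
  f <- wrap_deg(phase_deg) / 360
  ifelse(f > 0.5, f - 1, f)
}

#' Simulate tap times and an accelerometer trace for a cue schedule
#'
#' Each main beat spawns a tap with probability `1 - miss_prob`, at the cue
#' time plus a phase offset drawn from the configured von Mises distribution
#' and scaled by the ISI. The accelerometer trace is a sum of 60-ms biphasic
#' transients at the tap times plus white noise on all three axes.
#'
#' @param schedule A `cue_schedule`.
#' @param truth A `tap_ground_truth`.
#' @param seed RNG seed.
#' @param accel_fs Accelerometer sampling rate in Hz (default 1024).
#' @param snr Transient peak amplitude over noise SD (default 10).
#' @param transient_amp Peak acceleration of the dominant axis, m/s^2.
#' @return list(tap_times = list per sequence, accel = `accel_trace`,
#'   truth, schedule).
#' @export
simulate_taps <- function(schedule, truth = tap_ground_truth(), seed = 1,
                          accel_fs = 1024, snr = 10, transient_amp = 1) {
  stopifnot(inherits(schedule, "cue_schedule"),
            inherits(truth, "tap_ground_truth"))
  set.seed(seed)
  isi <- schedule$condition$isi
  taps <- lapply(schedule$main_beats, function(cues) {
    hit <- stats::runif(length(cues)) >= truth$miss_prob
    cues <- cues[hit]
    if (length(cues) == 0) return(numeric(0))
    ph <- if (is.infinite(truth$kappa)) {
      rep(truth$mean_phase_deg, length(cues))
    } else {
      rvonmises_deg(length(cues), truth$mean_phase_deg, truth$kappa)
    }
    t <- sort(cues + phase_to_frac(ph) * isi)
    # enforce a refractory gap so the train stays physically plausible
    if (length(t) > 1) {
      keep <- c(TRUE, diff(t) > 0.1 * isi)
      t <- t[keep]
    }
    t
  })

  dur <- max(schedule$sequence_windows) + 2 * isi + 1
  n <- ceiling(dur * accel_fs)
  tt <- (seq_len(n) - 1) / accel_fs
  axis_w <- c(1, 0.6, 0.3) * transient_amp
  # 60-ms biphasic transient, peak centred on the tap time
  half <- round(0.03 * accel_fs)
  ktime <- (-half:half) / accel_fs
  kernel <- cos(2 * pi * ktime / 0.06) *
    0.5 * (1 + cos(2 * pi * ktime / 0.06))
  pulse <- numeric(n)
  for (t in unlist(taps)) {
    ic <- round(t * accel_fs) + 1
    idx <- (ic - half):(ic + half)
    ok <- idx >= 1 & idx <= n
    pulse[idx[ok]] <- pulse[idx[ok]] + kernel[ok]
  }
  noise_sd <- transient_amp / snr
  samples <- vapply(axis_w, function(w) {
    w * pulse + stats::rnorm(n, sd = noise_sd)
  }, numeric(n))
  list(tap_times = taps, accel = accel_trace(t(samples), accel_fs),
       truth = truth, schedule = schedule)
}

#' Planted beta-band effect specification
#'
#' Describes the tap-locked beta-band power modulation planted in synthetic
#' EEG: dB values (re baseline) for the around-tap and after-tap windows at
#' the focus electrode, spreading over the scalp with a Gaussian weight in
#' spherical angle around the focus.
#'
#' @param around_db,after_db Planted power changes in dB at the focus
#'   electrode for the around-tap and after-tap windows.
#' @param focus Focus electrode label (default "C3").
#' @param spread_rad Angular SD (radians) of the Gaussian topographic
#'   weight; Inf plants the same dB everywhere (default 0.5).
#' @param band Beta band in Hz (default c(12, 30)); with the default
#'   broadband carrier the beta component is band-limited noise spanning
#'   this band, so every analysed wavelet sees the modulation.
#' @param carrier "band" (default; band-limited noise) or "sine" (a single
#'   sinusoid at `carrier_freq`, for narrowband experiments; note the
#'   band-averaged dB then dilutes the planted value).
#' @param carrier_freq Sinusoid frequency for `carrier = "sine"`
#'   (default 20 Hz; must lie within `band`).
#' @param beta_sigma_v Baseline SD of the beta component in volts
#'   (default 5e-6).
#' @param band_snr Beta-band power of the oscillatory component over the
#'   1/f background's power in the same band (default 10).
#' @param background_exponent 1/f^a exponent of the background (default 1).
#' @return A list of class `beta_effect_spec`.
#' @export
beta_effect_spec <- function(around_db = -1, after_db = 1, focus = "C3",
                             spread_rad = 0.5, band = c(12, 30),
                             carrier = c("band", "sine"), carrier_freq = 20,
                             beta_sigma_v = 5e-6, band_snr = 10,
                             background_exponent = 1) {
  carrier <- match.arg(carrier)
  stopifnot(is.finite(around_db), is.finite(after_db),
            band[1] < band[2], band_snr > 0,
            carrier_freq >= band[1], carrier_freq <= band[2])
  structure(list(around_db = around_db, after_db = after_db, focus = focus,
                 spread_rad = spread_rad, band = band, carrier = carrier,
                 carrier_freq = carrier_freq,
                 beta_sigma_v = beta_sigma_v, band_snr = band_snr,
                 background_exponent = background_exponent),
            class = "beta_effect_spec")
}

# topographic weights in [0, 1] for a montage around a focus electrode
topo_weights <- function(montage, focus, spread_rad) {
  pos <- as.matrix(montage[, c("x", "y", "z")])
  fi <- match(focus, montage$label)
  if (is.na(fi)) stop("focus electrode not in montage: ", focus)
  ang <- acos(pmin(pmax(pos %*% pos[fi, ], -1), 1))
  if (is.infinite(spread_rad)) rep(1, nrow(pos)) else
    as.numeric(exp(-ang^2 / (2 * spread_rad^2)))
}

# 1/f^a noise via FFT spectral shaping, unit variance
one_over_f_noise <- function(n, exponent, fs) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  freqs <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  gain <- c(0, 1 / freqs[-1]^(exponent / 2))
  shaped <- Re(stats::fft(spec * gain, inverse = TRUE)) / n
  shaped / stats::sd(shaped)
}

#' Simulate multichannel EEG with planted tap-locked beta modulation
#'
#' Per channel, the signal is a 1/f background plus a 12-30 Hz band-limited
#' noise component whose amplitude envelope equals baseline everywhere
#' except in the tap-locked windows `[-0.3, 0.2) * isi` (around-tap) and
#' `[0.2, 0.7) * isi` (after-tap), where it is scaled to the planted dB
#' values (weighted by the topographic profile).
#'
#' @param schedule A `cue_schedule`.
#' @param tap_times List of tap-time vectors per sequence (all taps must
#'   fall within one ISI of their sequence window).
#' @param spec A `beta_effect_spec`.
#' @param seed RNG seed.
#' @param fs Sampling rate in Hz (default 256).
#' @param montage Montage data.frame (default [default_montage()]).
#' @return An `eeg_recording` with the cue/tap event table attached and the
#'   planted per-channel dB targets in attribute "ground_truth".
#' @export
simulate_eeg <- function(schedule, tap_times, spec = beta_effect_spec(),
                         seed = 1, fs = 256, montage = default_montage()) {
  stopifnot(inherits(schedule, "cue_schedule"),
            inherits(spec, "beta_effect_spec"))
  isi <- schedule$condition$isi
  w <- schedule$sequence_windows
  for (k in seq_along(tap_times)) {
    t <- tap_times[[k]]
    if (length(t) && (any(t < w[k, 1] - isi) || any(t > w[k, 2] + isi))) {
      stop("taps outside sequence windows in sequence ", k)
    }
  }
  set.seed(seed)
  dur <- max(w) + 2 * isi + 1
  n <- ceiling(dur * fs)
  nch <- nrow(montage)
  weights <- topo_weights(montage, spec$focus, spec$spread_rad)
  db_around <- spec$around_db * weights
  db_after <- spec$after_db * weights

  # amplitude envelope template over time (per channel via planted dB)
  taps_all <- unlist(tap_times)
  tt <- (seq_len(n) - 1) / fs
  win_id <- integer(n)  # 0 none, 1 around, 2 after
  for (t in taps_all) {
    i1 <- which(tt >= t - 0.3 * isi & tt < t + 0.2 * isi)
    i2 <- which(tt >= t + 0.2 * isi & tt < t + 0.7 * isi)
    win_id[i1] <- 1L
    win_id[i2] <- 2L
  }

  # the planted dB is a statement about total band power (beta component
  # plus the 1/f background's share of the band), so the envelope gain
  # compensates for the unmodulated background: g^2 = (10^(d/10) (r+1) - 1)/r
  env_gain <- function(db) {
    g2 <- (10^(db / 10) * (spec$band_snr + 1) - 1) / spec$band_snr
    if (any(g2 < 0)) {
      stop("planted dB too negative for the configured band_snr")
    }
    sqrt(g2)
  }
  bf <- signal::butter(4, spec$band / (fs / 2), type = "pass")
  data <- matrix(0, nch, n)
  bg_scale <- NULL
  for (ch in seq_len(nch)) {
    bg <- one_over_f_noise(n, spec$background_exponent, fs)
    if (is.null(bg_scale)) {
      band_sd <- stats::sd(signal::filtfilt(bf, bg))
      bg_scale <- (spec$beta_sigma_v / sqrt(spec$band_snr)) / band_sd
    }
    beta <- if (spec$carrier == "sine") {
      sqrt(2) * sin(2 * pi * spec$carrier_freq * tt + stats::runif(1, 0, 2 * pi))
    } else {
      signal::filtfilt(bf, stats::rnorm(n))
    }
    beta <- beta / stats::sd(beta) * spec$beta_sigma_v
    env <- rep(1, n)
    env[win_id == 1L] <- env_gain(db_around[ch])
    env[win_id == 2L] <- env_gain(db_after[ch])
    data[ch, ] <- bg * bg_scale + beta * env
  }

  events <- rbind(
    data.frame(onset_s = unlist(schedule$main_beats), event_type = "main"),
    data.frame(onset_s = taps_all, event_type = "tap")
  )
  events$condition_label <- schedule$condition$label
  events <- events[order(events$onset_s), ]
  rec <- eeg_recording(data, fs, montage$label,
                       channel_positions = as.matrix(montage[, c("x", "y", "z")]),
                       events = events)
  attr(rec, "ground_truth") <- data.frame(
    channel = montage$label, around_db = db_around, after_db = db_after
  )
  rec
}

#' Inject square spikes into a recording (for artefact-rejection tests)
#' @param rec An `eeg_recording`.
#' @param times Spike onset times (s).
#' @param amplitude_v Spike amplitude in volts.
#' @param channel Channel index (default 1).
#' @param width_s Spike width (default 0.05 s).
#' @return The modified recording.
#' @export
inject_spikes <- function(rec, times, amplitude_v, channel = 1,
                          width_s = 0.05) {
  out <- rec
  n <- ncol(rec$data)
  for (t in times) {
    i0 <- round(t * rec$sample_rate) + 1
    idx <- i0:(i0 + round(width_s * rec$sample_rate))
    idx <- idx[idx >= 1 & idx <= n]
    out$data[channel, idx] <- out$data[channel, idx] + amplitude_v
  }
  out
}

#' Simulate a cell-observation table from a factorial effect structure
#'
#' Builds one observation per (frequency, modality, rhythmicity, electrode,
#' participant) cell as the sum of a grand mean, any provided effect
#' families (each must satisfy sum-to-zero over every one of its margins)
#' and Gaussian noise. This is the unit-test input for the hierarchical
#' factorial model.
#'
#' @param n_participants Number of participants (default 17).
#' @param electrodes Electrode labels (default the 30-channel montage);
#'   NULL builds a behavioural-style table without the electrode factor.
#' @param beta0 Grand mean.
#' @param effects Named list of effect arrays; names use factor letters
#'   F, M, R, E, P joined by ":" (e.g. "F", "F:E"). A main effect is a
#'   vector over that factor's levels; an interaction is an array with one
#'   dimension per factor, in the name's order.
#' @param noise_sd Observation noise SD (>= 0).
#' @param seed RNG seed.
#' @return data.frame(participant, frequency, modality, rhythmicity,
#'   electrode (unless NULL), value).
#' @export
simulate_cell_observations <- function(n_participants = 17,
                                       electrodes = default_montage()$label,
                                       beta0 = 0, effects = list(),
                                       noise_sd = 0.1, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  levels_list <- list(
    F = c("1Hz", "3Hz"), M = c("AUD", "VIS"), R = c("ISO", "POLY"),
    E = electrodes, P = paste0("P", seq_len(n_participants))
  )
  if (is.null(electrodes)) levels_list$E <- NULL
  grid <- expand.grid(levels_list, stringsAsFactors = FALSE)
  mu <- rep(beta0, nrow(grid))
  for (nm in names(effects)) {
    facs <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (!all(facs %in% names(levels_list))) {
      stop("unknown factor in effect name: ", nm)
    }
    eff <- effects[[nm]]
    dims <- vapply(levels_list[facs], length, integer(1))
    eff <- array(eff, dim = dims)
    for (d in seq_along(dims)) {
      others <- setdiff(seq_along(dims), d)
      msum <- if (length(others)) apply(eff, others, sum) else sum(eff)
      if (any(abs(msum) > 1e-8)) {
        stop("effect ", nm, " violates sum-to-zero over factor ", facs[d])
      }
    }
    idx <- as.matrix(
      do.call(cbind, lapply(facs, function(f) {
        match(grid[[f]], levels_list[[f]])
      }))
    )
    mu <- mu + eff[idx]
  }
  out <- data.frame(
    participant = grid$P,
    frequency = grid$F,
    modality = grid$M,
    rhythmicity = grid$R
  )
  if (!is.null(electrodes)) out$electrode <- grid$E
  out$value <- mu + stats::rnorm(nrow(grid), sd = noise_sd)
  out
}
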