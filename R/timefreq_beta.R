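# Morlet time-frequency analysis of the beta band: geometrically spaced
# wavelet family (12-32 Hz, 3-5 cycles, 11 steps), FFT convolution power,
# baseline segmentation, tap-locked epoching, the three artefact-rejection
# rules, decibel baseline normalization and around/after-tap window
# averaging into model-ready per-electrode cells.

#' Build the Morlet wavelet family
#'
#' Eleven centre frequencies geometrically spaced from 12 to 32 Hz, paired
#' index-wise with 3 to 5 cycles (also geometric): f_i = 12 (32/12)^(i/10),
#' c_i = 3 (5/3)^(i/10). Kernels are complex Morlets (Gaussian envelope SD
#' c_i / (2 pi f_i)) normalized to unit energy.
#'
#' @param fs Sampling rate in Hz (>= 128 so the family sits below Nyquist).
#' @param n_steps Number of wavelets (default 11).
#' @param f_range,cycle_range Frequency and cycle endpoints.
#' @return A list of class `wavelet_family`: freqs, cycles, fs, kernels
#'   (complex vectors), half_len (samples).
#' @export
build_wavelet_family <- function(fs, n_steps = 11, f_range = c(12, 32),
                                 cycle_range = c(3, 5)) {
  if (fs < 128) stop("sampling rate must be >= 128 Hz")
  i <- seq_len(n_steps) - 1
  freqs <- f_range[1] * (f_range[2] / f_range[1])^(i / (n_steps - 1))
  cycles <- cycle_range[1] * (cycle_range[2] / cycle_range[1])^(i / (n_steps - 1))
  kernels <- vector("list", n_steps)
  half_len <- integer(n_steps)
  for (k in seq_len(n_steps)) {
    sd_t <- cycles[k] / (2 * pi * freqs[k])
    hl <- ceiling(4 * sd_t * fs)
    tt <- (-hl:hl) / fs
    w <- exp(-tt^2 / (2 * sd_t^2)) * exp(2i * pi * freqs[k] * tt)
    w <- w / sqrt(sum(Mod(w)^2) / fs)  # unit energy
    kernels[[k]] <- w
    half_len[k] <- hl
  }
  structure(list(freqs = freqs, cycles = cycles, fs = fs,
                 kernels = kernels, half_len = half_len),
            class = "wavelet_family")
}

#' Continuous time-frequency power maps
#'
#' Complex Morlet convolution by spectral multiplication; power is the
#' squared magnitude of the coefficients. Samples within one kernel
#' half-length of either edge are flagged invalid per frequency.
#'
#' @param rec An `eeg_recording` (any reference scheme).
#' @param family A `wavelet_family` matching the recording's rate.
#' @return A list of class `tf_maps`: `power` (channels x freqs x time),
#'   `valid` (freqs x time logical), freqs, fs, channels.
#' @export
tf_power <- function(rec, family = build_wavelet_family(rec$sample_rate)) {
  if (abs(family$fs - rec$sample_rate) > 1e-9) {
    stop("wavelet family rate does not match the recording")
  }
  n <- ncol(rec$data)
  nch <- nrow(rec$data)
  nf <- length(family$freqs)
  klens <- vapply(family$kernels, length, integer(1))
  nfft <- stats::nextn(n + max(klens) - 1, 2)
  Kf <- lapply(family$kernels, function(k) stats::fft(c(k, rep(0, nfft - length(k)))))
  power <- array(NA_real_, c(nch, nf, n))
  for (ch in seq_len(nch)) {
    X <- stats::fft(c(rec$data[ch, ], rep(0, nfft - n)))
    for (f in seq_len(nf)) {
      conv <- stats::fft(X * Kf[[f]], inverse = TRUE) / nfft
      hl <- family$half_len[f]
      coef <- conv[(hl + 1):(hl + n)]
      power[ch, f, ] <- Mod(coef)^2
    }
  }
  valid <- matrix(TRUE, nf, n)
  for (f in seq_len(nf)) {
    hl <- family$half_len[f]
    valid[f, c(seq_len(hl), (n - hl + 1):n)] <- FALSE
  }
  structure(list(power = power, valid = valid, freqs = family$freqs,
                 fs = rec$sample_rate, channels = rec$channel_names),
            class = "tf_maps")
}

#' Baseline epoch definitions
#'
#' Splits the baseline window into 0.5-s epochs after trimming the first and
#' last second (a 15-s baseline yields 26 candidate epochs).
#'
#' @param fs Sampling rate (Hz).
#' @param baseline_window c(start, end) in seconds (>= 3 s long).
#' @param epoch_s Epoch duration (default 0.5).
#' @param trim_s Trim at each end (default 1).
#' @return data.frame(i0, i1, type = "baseline") of sample indices.
#' @export
baseline_epoch_defs <- function(fs, baseline_window, epoch_s = 0.5,
                                trim_s = 1) {
  dur <- diff(baseline_window)
  if (dur < 3) stop("baseline must be at least 3 s")
  t0 <- baseline_window[1] + trim_s
  t1 <- baseline_window[2] - trim_s
  n_ep <- floor((t1 - t0) / epoch_s + 1e-9)
  starts <- t0 + (seq_len(n_ep) - 1) * epoch_s
  data.frame(
    i0 = round(starts * fs) + 1L,
    i1 = round((starts + epoch_s) * fs),
    type = "baseline"
  )
}

#' Tap epoch definitions
#'
#' One epoch per tap spanning `[tap - isi, tap + isi]`.
#'
#' @param fs Sampling rate (Hz).
#' @param tap_times Vector of tap times (s).
#' @param isi Inter-stimulus interval (s).
#' @return data.frame(i0, i1, tap_time, type = "tap").
#' @export
tap_epoch_defs <- function(fs, tap_times, isi) {
  half <- round(isi * fs)
  center <- round(tap_times * fs) + 1L
  data.frame(i0 = center - half, i1 = center + half,
             tap_time = tap_times, type = "tap")
}

#' Three-rule artefact-epoch rejection
#'
#' Computed on the average-reference dataset and intended to be applied to
#' the Laplacian dataset. Channel-specific thresholds are derived from the
#' distribution of per-epoch statistics across all supplied epochs
#' (baseline and condition jointly). An epoch is rejected if, for any
#' channel, (1) its mean absolute amplitude, (2) its maximum absolute
#' amplitude, or (3) its maximum time-frequency power exceeds that
#' statistic's across-epoch mean + 2, 10 or 20 SD respectively. The union
#' over channels makes the 2-SD rule deliberately strict when many
#' channels fluctuate independently.
#'
#' @param rec Average-referenced `eeg_recording`.
#' @param tfp `tf_maps` for the same recording.
#' @param defs Epoch definitions (rbind of [baseline_epoch_defs()] and
#'   [tap_epoch_defs()] rows; extra columns are ignored).
#' @return Logical vector, TRUE = keep, one per epoch row.
#' @export
reject_artefact_epochs <- function(rec, tfp, defs) {
  nch <- nrow(rec$data)
  ne <- nrow(defs)
  n <- ncol(rec$data)
  stat_meanabs <- matrix(NA_real_, ne, nch)
  stat_maxabs <- matrix(NA_real_, ne, nch)
  stat_maxpow <- matrix(NA_real_, ne, nch)
  for (e in seq_len(ne)) {
    idx <- max(1L, defs$i0[e]):min(n, defs$i1[e])
    seg <- abs(rec$data[, idx, drop = FALSE])
    stat_meanabs[e, ] <- rowMeans(seg)
    stat_maxabs[e, ] <- apply(seg, 1, max)
    pow <- tfp$power[, , idx, drop = FALSE]
    stat_maxpow[e, ] <- apply(pow, 1, max)
  }
  # each rule thresholds its own statistic's across-epoch distribution at
  # mean + k SD per channel (k = 2, 10, 20); an epoch is rejected when any
  # channel violates any rule
  thr <- function(stat, k) {
    m <- colMeans(stat)
    s <- apply(stat, 2, stats::sd)
    s[is.na(s)] <- 0
    sweep(stat, 2, m + k * s, ">")
  }
  bad <- rowSums(thr(stat_meanabs, 2) | thr(stat_maxabs, 10) |
                   thr(stat_maxpow, 20)) > 0
  !bad
}

#' Baseline power spectrum
#'
#' Mean power per channel and frequency across the retained baseline
#' epochs.
#'
#' @param tfp `tf_maps` (typically the Laplacian dataset).
#' @param defs Baseline epoch definitions.
#' @param keep Logical vector of retained epochs (default all).
#' @return Channels x freqs matrix of strictly positive mean power.
#' @export
segment_baseline <- function(tfp, defs, keep = rep(TRUE, nrow(defs))) {
  defs <- defs[keep, , drop = FALSE]
  if (nrow(defs) == 0) stop("all baseline epochs rejected")
  n <- dim(tfp$power)[3]
  acc <- matrix(0, dim(tfp$power)[1], dim(tfp$power)[2])
  cnt <- 0L
  for (e in seq_len(nrow(defs))) {
    idx <- max(1L, defs$i0[e]):min(n, defs$i1[e])
    acc <- acc + apply(tfp$power[, , idx, drop = FALSE], c(1, 2), mean)
    cnt <- cnt + 1L
  }
  out <- acc / cnt
  dimnames(out) <- list(tfp$channels, NULL)
  out
}

#' Tap-locked time-frequency epochs
#'
#' One epoch per tap, `[tap - isi, tap + isi]`; epochs overlapping the
#' invalid convolution edges or the recording bounds are dropped.
#'
#' @param tfp `tf_maps`.
#' @param tap_times Vector (or list per sequence) of retained tap times.
#' @param isi Inter-stimulus interval (s).
#' @param keep Optional logical vector (e.g. from
#'   [reject_artefact_epochs()] rows for these taps).
#' @return A list of class `tf_epochs`: `power` (epochs x channels x freqs
#'   x time), `rel_times`, freqs, fs, channels, `n_dropped`.
#' @export
epoch_around_taps <- function(tfp, tap_times, isi, keep = NULL) {
  taps <- sort(unlist(tap_times))
  if (!is.null(keep)) {
    stopifnot(length(keep) == length(taps))
    taps <- taps[keep]
  }
  defs <- tap_epoch_defs(tfp$fs, taps, isi)
  n <- dim(tfp$power)[3]
  ok <- defs$i0 >= 1 & defs$i1 <= n
  # also require every sample valid for every frequency
  for (e in which(ok)) {
    if (!all(tfp$valid[, defs$i0[e]:defs$i1[e]])) ok[e] <- FALSE
  }
  if (!any(ok)) stop("no valid tap epochs")
  defs <- defs[ok, , drop = FALSE]
  nw <- defs$i1[1] - defs$i0[1] + 1L
  out <- array(NA_real_, c(nrow(defs), dim(tfp$power)[1],
                           dim(tfp$power)[2], nw))
  for (e in seq_len(nrow(defs))) {
    out[e, , , ] <- tfp$power[, , defs$i0[e]:defs$i1[e]]
  }
  structure(list(power = out,
                 rel_times = ((seq_len(nw) - 1) - (nw - 1) / 2) / tfp$fs,
                 freqs = tfp$freqs, fs = tfp$fs, channels = tfp$channels,
                 n_dropped = sum(!ok)),
            class = "tf_epochs")
}

#' Decibel normalization against the baseline spectrum
#'
#' POW(t, f) = 10 log10(tap(t, f) / baseline(f)), per channel and
#' frequency.
#'
#' @param epochs A `tf_epochs` of raw power.
#' @param baseline Channels x freqs baseline matrix (strictly positive).
#' @return The epochs with power replaced by dB values.
#' @export
db_normalize <- function(epochs, baseline) {
  if (any(baseline <= 0)) stop("baseline power must be strictly positive")
  d <- dim(epochs$power)
  out <- epochs
  bl <- array(rep(baseline, each = d[1]), dim = d[1:3])
  for (tt in seq_len(d[4])) {
    out$power[, , , tt] <- 10 * log10(epochs$power[, , , tt] / bl)
  }
  out$unit <- "dB"
  out
}

#' Tap-locked analysis window boundaries
#'
#' Epochs are trimmed to one ISI with 30% before and 70% after the tap;
#' the around-tap window spans the first half-second fractions
#' `[-0.3, 0.2) * isi` and the after-tap window `[0.2, 0.7) * isi`
#' (so -0.3 to 0.2 s and 0.2 to 0.7 s at 1 Hz).
#'
#' @param isi Inter-stimulus interval (s).
#' @return list(trim = c(lo, hi), around = c(lo, hi), after = c(lo, hi)),
#'   in seconds relative to the tap.
#' @export
analysis_windows <- function(isi) {
  list(trim = c(-0.3, 0.7) * isi,
       around = c(-0.3, 0.2) * isi,
       after = c(0.2, 0.7) * isi)
}

#' Around/after-tap window averages per electrode
#'
#' Trims each epoch to one ISI split 30/70 around the tap
#' (`[-0.3, 0.7) * isi`), then averages dB power over time within the
#' around-tap window `[-0.3, 0.2) * isi` and the after-tap window
#' `[0.2, 0.7) * isi`, over the wavelets with centre frequency in
#' `[12, band_max]` Hz (the 32-Hz wavelet is excluded from the beta-band
#' average by default), and over epochs.
#'
#' @param epochs dB-normalized `tf_epochs`.
#' @param isi Inter-stimulus interval (s).
#' @param band_max Upper band edge for averaging (default 30).
#' @return data.frame(channel, window, value_db) with one row per channel
#'   and window ("around", "after").
#' @export
window_average <- function(epochs, isi, band_max = 30) {
  rt <- epochs$rel_times
  fsel <- epochs$freqs >= 12 & epochs$freqs <= band_max
  win <- analysis_windows(isi)
  around <- rt >= win$around[1] & rt < win$around[2]
  after <- rt >= win$after[1] & rt < win$after[2]
  # average the linear power ratio over epochs and time, then express in
  # dB, then average across the band's wavelets; averaging raw per-sample
  # dB instead would be biased low by the log of the noisy ratio
  avg <- function(tsel) {
    lin <- 10^(epochs$power[, , fsel, tsel, drop = FALSE] / 10)
    per_cf <- apply(lin, c(2, 3), mean)
    rowMeans(10 * log10(per_cf))
  }
  data.frame(
    channel = rep(epochs$channels, 2),
    window = rep(c("around", "after"), each = length(epochs$channels)),
    value_db = c(avg(around), avg(after))
  )
}
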