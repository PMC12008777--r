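# EEG conditioning: zero-phase Butterworth band-pass, channel quality
# control, Perrin spherical-spline interpolation, average reference and
# spherical-spline surface Laplacian.

# Fourier-domain rate conversion: exact for band-limited signals (every
# call site band-passes below the target Nyquist first), with the Nyquist
# bin zeroed so downsampling can never alias.
resample_1d <- function(x, fs_from, fs_to) {
  if (fs_from == fs_to) return(x)
  n <- length(x)
  m <- round(n * fs_to / fs_from)
  X <- stats::fft(x)
  Y <- complex(m)
  half <- if (m %% 2 == 0) m %/% 2 - 1 else (m - 1) %/% 2
  half <- min(half, if (n %% 2 == 0) n %/% 2 - 1 else (n - 1) %/% 2)
  Y[1:(half + 1)] <- X[1:(half + 1)]
  if (half >= 1) Y[(m - half + 1):m] <- X[(n - half + 1):n]
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Zero-phase Butterworth band-pass and rate conversion for EEG
#'
#' Applies a forward-backward (zero-phase) second-order Butterworth band-pass
#' at the native rate, then downsamples with an anti-aliased polyphase
#' resampler.
#'
#' @param rec An `eeg_recording`.
#' @param lo,hi Band edges in Hz (defaults 1 and 35).
#' @param order Butterworth order (default 2).
#' @param downsample_to Target rate in Hz (default 256; NULL keeps the rate).
#' @return A filtered `eeg_recording`.
#' @export
bandpass_eeg <- function(rec, lo = 1, hi = 35, order = 2,
                         downsample_to = 256) {
  fs <- rec$sample_rate
  if (fs <= 2 * hi) stop("sample rate must exceed twice the upper band edge")
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  filt <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  if (!is.null(downsample_to) && downsample_to != fs) {
    filt <- t(apply(filt, 1, resample_1d, fs_from = fs, fs_to = downsample_to))
    fs <- downsample_to
  }
  out <- rec
  out$data <- filt
  out$sample_rate <- fs
  out
}

#' Flag artefactual channels by mean absolute amplitude
#'
#' A channel is flagged when its whole-recording mean absolute amplitude is
#' above 50 uV (poor contact / movement) or below 1 uV (flat or
#' disconnected).
#'
#' @param rec An `eeg_recording` in volts.
#' @param hi_uv,lo_uv Thresholds in microvolts (defaults 50 and 1).
#' @return Logical vector, one per channel, named by channel.
#' @export
flag_bad_channels <- function(rec, hi_uv = 50, lo_uv = 1) {
  amp_uv <- rowMeans(abs(rec$data)) * 1e6
  flags <- amp_uv > hi_uv | amp_uv < lo_uv
  names(flags) <- rec$channel_names
  flags
}

# Legendre-series kernels for spherical splines (Perrin-style).
# g: interpolation kernel, series (2n+1)/(n(n+1))^m * Pn(x) / 4pi
# h: Laplacian kernel, series (2n+1)/(n(n+1))^(m-1) * Pn(x) / 4pi
spline_kernels <- function(x, m = 4, nmax = 50) {
  x <- pmin(pmax(x, -1), 1)
  g <- matrix(0, nrow = NROW(x), ncol = NCOL(x))
  h <- g
  p_nm1 <- matrix(1, nrow = NROW(x), ncol = NCOL(x))  # P0
  p_n <- x                                            # P1
  for (n in 1:nmax) {
    fac <- (2 * n + 1) / (n * (n + 1))^m
    g <- g + fac * p_n
    h <- h + fac * (n * (n + 1)) * p_n
    # advance recurrence: P_{n+1} = ((2n+1) x P_n - n P_{n-1}) / (n+1)
    p_np1 <- ((2 * n + 1) * x * p_n - n * p_nm1) / (n + 1)
    p_nm1 <- p_n
    p_n <- p_np1
  }
  list(g = g / (4 * pi), h = h / (4 * pi))
}

cosine_angles <- function(pos_a, pos_b) {
  tcrossprod(as.matrix(pos_a), as.matrix(pos_b))
}

#' Spherical-spline interpolation of flagged channels
#'
#' Replaces flagged channels with Perrin-style spherical-spline estimates
#' (stiffness m = 4) from the remaining channels, sample by sample.
#'
#' @param rec An `eeg_recording` with channel positions.
#' @param flags Logical vector from [flag_bad_channels()].
#' @param m Spline stiffness (default 4).
#' @param nmax Legendre series order (default 50).
#' @param lambda Ridge regularization on the spline system (default 1e-5).
#' @param max_bad_frac Maximum tolerated fraction of flagged channels
#'   (default 0.2).
#' @return The recording with flagged channels replaced.
#' @export
interpolate_channels <- function(rec, flags, m = 4, nmax = 50,
                                 lambda = 1e-5, max_bad_frac = 0.2) {
  if (is.null(rec$channel_positions)) stop("recording has no channel positions")
  if (!any(flags)) return(rec)
  if (mean(flags) > max_bad_frac) {
    stop("too many flagged channels to interpolate (", sum(flags), ")")
  }
  pos <- rec$channel_positions
  good <- which(!flags); bad <- which(flags)
  Ggg <- spline_kernels(cosine_angles(pos[good, , drop = FALSE],
                                      pos[good, , drop = FALSE]),
                        m = m, nmax = nmax)$g
  Gbg <- spline_kernels(cosine_angles(pos[bad, , drop = FALSE],
                                      pos[good, , drop = FALSE]),
                        m = m, nmax = nmax)$g
  ng <- length(good)
  A <- rbind(cbind(Ggg + lambda * diag(ng), rep(1, ng)),
             c(rep(1, ng), 0))
  rhs <- rbind(rec$data[good, , drop = FALSE],
               rep(0, ncol(rec$data)))
  sol <- solve(A, rhs)
  cs <- sol[seq_len(ng), , drop = FALSE]
  c0 <- sol[ng + 1, ]
  est <- Gbg %*% cs + matrix(c0, nrow = length(bad), ncol = ncol(rec$data),
                             byrow = TRUE)
  out <- rec
  out$data[bad, ] <- est
  out
}

#' Average reference
#'
#' Subtracts the instantaneous channel mean from every channel, so the
#' channel sum is (numerically) zero afterwards.
#'
#' @param rec An `eeg_recording` with at least 2 channels.
#' @return The re-referenced recording.
#' @export
rereference_average <- function(rec) {
  if (nrow(rec$data) < 2) stop("need at least 2 channels")
  out <- rec
  out$data <- sweep(rec$data, 2, colMeans(rec$data))
  out
}

#' Spherical-spline surface Laplacian (current source density)
#'
#' Reference-free spatial filter: fits a spherical spline (stiffness m = 4,
#' Legendre series to order `nmax`, ridge `lambda`) to each time sample and
#' evaluates its surface Laplacian at the electrodes, scaled by the head
#' radius to V/m^2. Output is positive at focal sources by convention.
#'
#' @param rec An `eeg_recording` with unit-sphere channel positions.
#' @param m Spline stiffness (default 4).
#' @param lambda Ridge regularization (default 1e-5).
#' @param nmax Legendre series order (default 50).
#' @param head_radius_m Head radius in metres (default 0.09).
#' @return An `eeg_recording` with unit "V/m2".
#' @export
surface_laplacian <- function(rec, m = 4, lambda = 1e-5, nmax = 50,
                              head_radius_m = 0.09) {
  if (is.null(rec$channel_positions)) stop("recording has no channel positions")
  nch <- nrow(rec$data)
  if (nch < 16) stop("need at least 16 channels with positions")
  K <- spline_kernels(cosine_angles(rec$channel_positions,
                                    rec$channel_positions),
                      m = m, nmax = nmax)
  Ginv <- solve(K$g + lambda * diag(nch))
  ones <- rep(1, nch)
  gi1 <- Ginv %*% ones
  denom <- sum(gi1)
  # spline coefficients with the sum-to-zero constraint, per sample
  V <- rec$data
  C <- Ginv %*% V - gi1 %*% ((crossprod(gi1, V)) / denom)
  out <- rec
  out$data <- (t(K$h) %*% C) / head_radius_m^2
  out$unit <- "V/m2"
  out
}
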