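# Tap detection from accelerometry: L2 magnitude, zero-phase band-pass and
# rate conversion, sliding-window peak picking anchored to cues and then to
# detected taps, and the sequence/condition retention rules.

#' Euclidean magnitude of a 3-axis accelerometer trace
#' @param trace An `accel_trace` (3 x N).
#' @return Numeric vector of pointwise L2 norms.
#' @export
accel_magnitude <- function(trace) {
  if (!inherits(trace, "accel_trace")) stop("trace must be an accel_trace")
  sqrt(colSums(trace$samples^2))
}

#' Band-pass filter and downsample an accelerometer magnitude trace
#'
#' Forward-backward second-order Butterworth band-pass at 0.5-70 Hz at the
#' native rate, then anti-aliased polyphase resampling to 256 Hz.
#'
#' @param mag 1-D magnitude trace.
#' @param fs Native sampling rate in Hz (> 140 so the 70-Hz cut-off stays
#'   below Nyquist).
#' @param lo,hi Band edges in Hz (defaults 0.5 and 70).
#' @param target_fs Output rate (default 256).
#' @return list(x, fs) with the processed trace at `target_fs`.
#' @export
preprocess_accel <- function(mag, fs, lo = 0.5, hi = 70, target_fs = 256) {
  if (fs <= 140) stop("sampling rate must exceed 140 Hz")
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, as.numeric(mag))
  x <- resample_1d(x, fs, target_fs)
  list(x = x, fs = target_fs)
}

# largest local maximum above a threshold inside [i0, i1]; earliest wins ties
window_peak <- function(x, i0, i1, min_peak) {
  i0 <- max(i0, 2L); i1 <- min(i1, length(x) - 1L)
  if (i1 <= i0) return(NA_integer_)
  seg <- i0:i1
  is_max <- x[seg] >= x[seg - 1L] & x[seg] >= x[seg + 1L] & x[seg] > min_peak
  if (!any(is_max)) return(NA_integer_)
  cand <- seg[is_max]
  cand[which.max(x[cand])]  # which.max returns the first (earliest) maximum
}

#' Detect finger taps with a cue-anchored sliding window
#'
#' The first window is centred on the first cue (`[cue - isi/2, cue +
#' isi/2]`); the highest local maximum above `min_peak` in the window is a
#' tap. If no peak is found the next window is centred on the next cue.
#' After a detection, the next window is `[tap + isi/2, tap + 1.5 isi]`, so
#' windows track the performed rhythm, not the cue train.
#'
#' @param x Processed magnitude trace (from [preprocess_accel()]).
#' @param fs Sampling rate of `x` in Hz.
#' @param cue_times Main-beat times in seconds (nonempty).
#' @param isi Inter-stimulus interval in seconds (> 0).
#' @param min_peak Amplitude threshold; default 5 x the median absolute
#'   deviation of the trace.
#' @return Numeric vector of tap times in seconds.
#' @export
detect_taps <- function(x, fs, cue_times, isi, min_peak = NULL) {
  if (length(x) == 0) stop("empty trace")
  if (length(cue_times) == 0) stop("cue_times must be nonempty")
  if (isi <= 0) stop("isi must be > 0")
  if (is.null(min_peak)) min_peak <- 5 * stats::mad(x)
  t_end <- (length(x) - 1) / fs
  taps <- numeric(0)
  cue_idx <- 1L
  mode_cue <- TRUE
  next_start <- NA_real_
  repeat {
    if (mode_cue) {
      if (cue_idx > length(cue_times)) break
      center <- cue_times[cue_idx]
      w0 <- center - 0.5 * isi
      w1 <- center + 0.5 * isi
    } else {
      w0 <- next_start
      w1 <- next_start + isi
      if (w0 > max(t_end, cue_times[length(cue_times)] + 0.5 * isi)) break
    }
    pk <- window_peak(x, round(w0 * fs) + 1L, round(w1 * fs) + 1L, min_peak)
    if (is.na(pk)) {
      if (!mode_cue) {
        # lost the rhythm: fall back to the next cue after the last window
        cue_idx <- which(cue_times > w0 + 0.5 * isi)[1]
        if (is.na(cue_idx)) break
        mode_cue <- TRUE
      } else {
        cue_idx <- cue_idx + 1L
      }
    } else {
      tap_t <- (pk - 1) / fs
      taps <- c(taps, tap_t)
      next_start <- tap_t + 0.5 * isi
      mode_cue <- FALSE
    }
  }
  taps
}

#' Detect taps per sequence of a cue schedule
#'
#' Runs [detect_taps()] independently for each sequence's cue train,
#' restricting to peaks within half an ISI of the sequence window.
#'
#' @param x Processed magnitude trace.
#' @param fs Sampling rate (Hz).
#' @param schedule A `cue_schedule`.
#' @param min_peak Threshold passed to [detect_taps()].
#' @return List of tap-time vectors, one per sequence.
#' @export
detect_taps_by_sequence <- function(x, fs, schedule, min_peak = NULL) {
  isi <- schedule$condition$isi
  lapply(seq_len(nrow(schedule$sequence_windows)), function(k) {
    detect_taps(x, fs, schedule$main_beats[[k]], isi, min_peak)
  })
}

#' Apply the sequence and condition retention rules
#'
#' A sequence is retained iff its raw tap count lies within 30% of the cue
#' count, realized as the integer interval `[ceil(0.7 C), floor(1.3 C)]`
#' (12-20 taps for 16 cues, 36-66 for 51 cues). The whole condition is
#' dropped when 4 or more of the 5 sequences fail. The first two taps of
#' each retained sequence are removed before any metric is computed.
#'
#' @param taps_by_seq List of tap-time vectors per sequence.
#' @param cues_per_sequence Number of cues per sequence.
#' @param n_sequences Expected number of sequences (default 5).
#' @return A list of class `tap_series`: `tap_times` (start-up taps
#'   removed, non-retained sequences emptied), `raw_counts`, `retained`
#'   (per sequence), `condition_retained`, `bounds`.
#' @export
apply_retention_rules <- function(taps_by_seq, cues_per_sequence,
                                  n_sequences = 5) {
  if (length(taps_by_seq) != n_sequences) {
    stop("expected ", n_sequences, " sequences, got ", length(taps_by_seq))
  }
  lo <- ceiling(0.7 * cues_per_sequence)
  hi <- floor(1.3 * cues_per_sequence)
  counts <- vapply(taps_by_seq, length, integer(1))
  retained <- counts >= lo & counts <= hi
  condition_retained <- sum(!retained) < 4
  kept <- lapply(seq_along(taps_by_seq), function(k) {
    if (!retained[k]) return(numeric(0))
    t <- taps_by_seq[[k]]
    if (length(t) > 2) t[-(1:2)] else numeric(0)
  })
  structure(
    list(tap_times = kept, raw_counts = counts, retained = retained,
         condition_retained = condition_retained, bounds = c(lo, hi)),
    class = "tap_series"
  )
}

#' @export
print.tap_series <- function(x, ...) {
  cat(sprintf("<tap_series: counts [%s], retained %d/%d, condition %s>\n",
              paste(x$raw_counts, collapse = ", "), sum(x$retained),
              length(x$retained),
              if (x$condition_retained) "retained" else "excluded"))
  invisible(x)
}

#' Write detected taps to TSV
#' @param series A `tap_series`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_taps_tsv <- function(series, path) {
  rows <- do.call(rbind, lapply(seq_along(series$tap_times), function(k) {
    t <- series$tap_times[[k]]
    if (length(t) == 0) return(NULL)
    data.frame(sequence = k, tap_time_s = t, retained = series$retained[k])
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
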