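# Behavioural synchronization metrics: inter-tap intervals, ITI discrepancy
# and variability, circular tap phases, resultant vectors, circular
# median/IQR, phase-to-asynchrony conversion and cue-tap cross-correlograms.

#' Inter-tap intervals
#' @param tap_times Strictly increasing tap times in seconds.
#' @return First differences in seconds.
#' @export
inter_tap_intervals <- function(tap_times) {
  if (length(tap_times) < 2) stop("need at least 2 taps")
  if (any(diff(tap_times) <= 0)) stop("tap_times must be strictly increasing")
  diff(tap_times)
}

#' Inter-tap-interval discrepancy (ITI-D)
#'
#' Mean inter-tap interval divided by the cue inter-stimulus interval. 1 means
#' tapping at the cued rate; above/below 1 means tapping too slowly/fast.
#'
#' @param itis Inter-tap intervals in seconds.
#' @param isi Cue inter-stimulus interval in seconds.
#' @return A unitless ratio.
#' @export
iti_discrepancy <- function(itis, isi) {
  if (isi <= 0) stop("isi must be > 0")
  if (length(itis) == 0) stop("empty itis")
  mean(itis) / isi
}

#' Inter-tap-interval coefficient of variation (ITI-CV)
#'
#' Sample standard deviation of the intervals divided by their mean,
#' times 100. Zero for perfectly regular tapping.
#'
#' @param itis Inter-tap intervals in seconds (at least 2).
#' @return Percentage.
#' @export
iti_cv <- function(itis) {
  if (length(itis) < 2) stop("need at least 2 intervals")
  m <- mean(itis)
  if (m <= 0) stop("mean interval must be > 0")
  stats::sd(itis) / m * 100
}

#' Circular tap phases relative to the cue train
#'
#' Each tap is expressed on a 0-360 degree circle between its preceding and
#' successive main beat: phase = 360 * (tap - preceding) / (successive -
#' preceding). The denominator uses the actual bracketing inter-cue interval.
#' Taps before the first or after the last main beat are dropped and counted.
#'
#' @param tap_times Tap times in seconds.
#' @param main_beats Main-beat times in seconds (sorted).
#' @return A list of class `phase_set`: `phases` (degrees in [0, 360)),
#'   `mean_angle`, `R`, `n_dropped`.
#' @export
tap_phases <- function(tap_times, main_beats) {
  if (length(main_beats) < 2) stop("need at least 2 main beats")
  keep <- tap_times >= main_beats[1] & tap_times < main_beats[length(main_beats)]
  dropped <- sum(!keep)
  taps <- tap_times[keep]
  if (length(taps) == 0) stop("no taps bracketed by cues")
  idx <- findInterval(taps, main_beats)
  lo <- main_beats[idx]
  hi <- main_beats[idx + 1]
  phases <- wrap_deg(360 * (taps - lo) / (hi - lo))
  res <- circ_resultant(phases)
  structure(
    list(phases = phases, mean_angle = res$mean_deg, R = res$R,
         n_dropped = dropped),
    class = "phase_set"
  )
}

#' Mean resultant vector of a set of phases
#' @param phases_deg Angles in degrees.
#' @return list(R, mean_angle) with R in [0, 1].
#' @export
resultant_vector <- function(phases_deg) {
  if (length(phases_deg) == 0) stop("empty phases")
  res <- circ_resultant(phases_deg)
  list(R = res$R, mean_angle = res$mean_deg)
}

#' Circular median and interquartile range
#'
#' The circular median minimizes the summed circular absolute deviation; ties
#' are resolved by the circular mean of the minimizers. Quartiles are computed
#' after rotating the median to 180 degrees (avoiding wrap ambiguity) and
#' rotated back.
#'
#' @param angles_deg At least 3 angles in degrees.
#' @return list(median_deg, iqr_deg = c(lo, hi)).
#' @export
circular_median_iqr <- function(angles_deg) {
  n <- length(angles_deg)
  if (n < 3) stop("need at least 3 angles")
  a <- wrap_deg(angles_deg)
  # candidate minimizers: the data points and all pairwise circular midpoints
  mids <- outer(a, a, function(x, y) wrap_deg(x + wrap_deg(y - x) / 2))
  cand <- unique(c(a, as.vector(mids)))
  obj <- vapply(cand, function(m) sum(circ_dist_deg(a, m)), numeric(1))
  best <- cand[abs(obj - min(obj)) < 1e-9]
  med <- if (length(best) == 1) best else circ_resultant(best)$mean_deg
  rot <- wrap_deg(a - med + 180)
  q <- stats::quantile(rot, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- wrap_deg(q + med - 180)
  list(median_deg = wrap_deg(med), iqr_deg = iqr)
}

#' Convert a circular phase to a signed asynchrony in milliseconds
#'
#' Phases at or below 180 degrees map to positive (late) asynchronies,
#' phases above 180 map to negative (early) asynchronies; e.g. 330 degrees at
#' a 1-s ISI is -83 ms. Rounded to the nearest millisecond.
#'
#' @param phase_deg Phase in [0, 360).
#' @param isi Inter-stimulus interval in seconds.
#' @return Signed integer milliseconds.
#' @export
phase_to_asynchrony_ms <- function(phase_deg, isi) {
  if (any(phase_deg < 0 | phase_deg >= 360)) stop("phase must be in [0, 360)")
  if (isi <= 0) stop("isi must be > 0")
  signed <- ifelse(phase_deg <= 180, phase_deg, phase_deg - 360)
  round(signed / 360 * isi * 1000)
}

#' Effective tapping rate implied by an ITI discrepancy
#'
#' Tapping at an ITI-D above 1 means tapping slower than the cue: the
#' performed rate is the cue rate divided by the discrepancy (e.g. a 3.2-Hz
#' cue tapped with ITI-D 1.03 is an effective 3.1 Hz).
#'
#' @param main_rate Cue rate in Hz.
#' @param iti_d Inter-tap-interval discrepancy.
#' @return Effective rate in Hz.
#' @export
effective_rate <- function(main_rate, iti_d) {
  if (any(iti_d <= 0)) stop("iti_d must be > 0")
  main_rate / iti_d
}

#' Cue-tap cross-correlogram
#'
#' Binned impulse-train cross-correlation of tap and cue times over lags in
#' [-isi/2, +isi/2], divided by the number of taps, so coincident trains give
#' a value of 1 at lag 0.
#'
#' @param tap_times Tap times (s).
#' @param main_beats Cue times (s).
#' @param isi Inter-stimulus interval (s).
#' @param bin Bin width in seconds (default 1/256, the processing rate).
#' @return data.frame(lag_s, value).
#' @export
cross_correlogram <- function(tap_times, main_beats, isi, bin = 1 / 256) {
  if (length(tap_times) == 0 || length(main_beats) == 0) stop("empty train")
  max_lag <- isi / 2
  edges <- seq(-max_lag - bin / 2, max_lag + bin / 2, by = bin)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  lags <- as.vector(outer(tap_times, main_beats, "-"))
  lags <- lags[lags >= edges[1] & lags <= edges[length(edges)]]
  counts <- if (length(lags)) {
    tabulate(findInterval(lags, edges, rightmost.closed = TRUE),
             nbins = length(centers))
  } else {
    rep(0L, length(centers))
  }
  data.frame(lag_s = centers, value = counts / length(tap_times))
}

#' Per-participant behavioural summary for one condition
#'
#' Pools retained sequences: inter-tap intervals are computed within each
#' sequence (never across sequence breaks), then pooled for ITI-D/ITI-CV;
#' phases are pooled across sequences for the resultant vector.
#'
#' @param taps_by_seq List of tap-time vectors, one per retained sequence.
#' @param schedule The `cue_schedule` the taps follow.
#' @return data.frame(iti_d, iti_cv, mean_phase_deg, R, n_taps).
#' @export
behaviour_summary <- function(taps_by_seq, schedule) {
  isi <- schedule$condition$isi
  itis <- unlist(lapply(taps_by_seq, function(t) {
    if (length(t) >= 2) inter_tap_intervals(t) else numeric(0)
  }))
  phases <- unlist(lapply(seq_along(taps_by_seq), function(k) {
    t <- taps_by_seq[[k]]
    if (length(t) == 0) return(numeric(0))
    tap_phases(t, schedule$main_beats[[k]])$phases
  }))
  res <- resultant_vector(phases)
  data.frame(
    iti_d = iti_discrepancy(itis, isi),
    iti_cv = iti_cv(itis),
    mean_phase_deg = res$mean_angle,
    R = res$R,
    n_taps = length(unlist(taps_by_seq))
  )
}
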