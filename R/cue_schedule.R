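#' Construct a single cue condition
#'
#' A cue condition is one cell of the 2x2x2 experimental design crossing cue
#' frequency (slow = 1 Hz, fast = 3.2 Hz), cue modality (auditory, visual) and
#' cue rhythmicity (isorhythmic, polyrhythmic). The fast auditory-polyrhythmic
#' condition runs at 3.0 Hz rather than 3.2 Hz, mirroring the stimulus set the
#' design is modelled on.
#'
#' @param frequency_class "slow" or "fast".
#' @param modality "auditory" or "visual".
#' @param rhythmicity "iso" or "poly".
#' @return An object of class `cue_condition` with fields `frequency_class`,
#'   `modality`, `rhythmicity`, `main_rate` (events/s), `isi` (s),
#'   `cues_per_sequence` and `label` (e.g. "AUD-POLY-3Hz").
#' @export
cue_condition <- function(frequency_class = c("slow", "fast"),
                          modality = c("auditory", "visual"),
                          rhythmicity = c("iso", "poly")) {
  frequency_class <- match.arg(frequency_class)
  modality <- match.arg(modality)
  rhythmicity <- match.arg(rhythmicity)

  main_rate <- if (frequency_class == "slow") {
    1.0
  } else if (modality == "auditory" && rhythmicity == "poly") {
    3.0  # stimulus-code quirk: fast AUD-POLY ran at 3.0 Hz, not 3.2 Hz
  } else {
    3.2
  }
  cues_per_sequence <- if (frequency_class == "slow") 16L else 51L
  label <- paste0(
    if (modality == "auditory") "AUD" else "VIS", "-",
    toupper(rhythmicity), "-",
    if (frequency_class == "slow") "1Hz" else "3Hz"
  )
  structure(
    list(
      frequency_class = frequency_class,
      modality = modality,
      rhythmicity = rhythmicity,
      main_rate = main_rate,
      isi = 1 / main_rate,
      cues_per_sequence = cues_per_sequence,
      label = label
    ),
    class = "cue_condition"
  )
}

#' @export
print.cue_condition <- function(x, ...) {
  cat(sprintf("<cue_condition %s: %.4g Hz, ISI %.4g s, %d cues/sequence>\n",
              x$label, x$main_rate, x$isi, x$cues_per_sequence))
  invisible(x)
}

#' Build the full 2x2x2 condition set
#'
#' @return A list of 8 `cue_condition` objects, named by label.
#' @export
build_condition_set <- function() {
  grid <- expand.grid(
    frequency_class = c("slow", "fast"),
    modality = c("auditory", "visual"),
    rhythmicity = c("iso", "poly"),
    stringsAsFactors = FALSE
  )
  out <- lapply(seq_len(nrow(grid)), function(i) {
    cue_condition(grid$frequency_class[i], grid$modality[i], grid$rhythmicity[i])
  })
  names(out) <- vapply(out, function(x) x$label, character(1))
  out
}

#' Look up a condition by label
#' @param label e.g. "AUD-ISO-1Hz".
#' @return A `cue_condition`.
#' @export
condition_by_label <- function(label) {
  set <- build_condition_set()
  if (!label %in% names(set)) {
    stop("unknown condition label: ", label)
  }
  set[[label]]
}

#' Visual cue flash duration for a condition
#'
#' Visual cues are lit for half the inter-stimulus interval; auditory cues
#' last a fixed 0.15 s.
#' @param condition A `cue_condition`.
#' @return Duration in seconds.
#' @export
cue_duration <- function(condition) {
  if (condition$modality == "visual") condition$isi / 2 else 0.15
}

#' Generate the deterministic cue timeline for one condition
#'
#' The timeline starts with a 15-s resting baseline, then `n_sequences`
#' tapping sequences separated by 5-s breaks. Within a sequence the main
#' beats start at the sequence start and step by the ISI for
#' `cues_per_sequence` events, so a sequence spans
#' `(cues_per_sequence - 1) * isi` seconds. Polyrhythmic conditions add a
#' secondary beat train at 1.5x the main rate (2:3 relationship), phase
#' anchored so the first secondary beat coincides with the first main beat,
#' and emitted only up to the last main beat.
#'
#' @param condition A `cue_condition`.
#' @param n_sequences Number of tapping sequences (default 5).
#' @param baseline_s Baseline duration in seconds (default 15).
#' @param break_s Inter-sequence break in seconds (default 5).
#' @return An object of class `cue_schedule` with `main_beats` and
#'   `secondary_beats` (lists of numeric vectors, one per sequence),
#'   `sequence_windows` (n x 2 matrix), `baseline_window` (length-2 vector)
#'   and `condition`.
#' @export
generate_cue_schedule <- function(condition, n_sequences = 5,
                                  baseline_s = 15, break_s = 5) {
  if (!inherits(condition, "cue_condition")) {
    stop("condition must be a cue_condition")
  }
  if (!is.numeric(n_sequences) || n_sequences < 1) {
    stop("n_sequences must be >= 1")
  }
  n_sequences <- as.integer(n_sequences)
  isi <- condition$isi
  n_cues <- condition$cues_per_sequence
  seq_dur <- (n_cues - 1) * isi

  main_beats <- vector("list", n_sequences)
  secondary_beats <- vector("list", n_sequences)
  windows <- matrix(NA_real_, n_sequences, 2,
                    dimnames = list(NULL, c("start", "end")))
  t0 <- baseline_s
  for (k in seq_len(n_sequences)) {
    start <- t0 + (k - 1) * (seq_dur + break_s)
    main_beats[[k]] <- start + (seq_len(n_cues) - 1) * isi
    windows[k, ] <- c(start, start + seq_dur)
    if (condition$rhythmicity == "poly") {
      step <- isi / 1.5
      n_sec <- floor(seq_dur / step + 1e-9) + 1
      secondary_beats[[k]] <- start + (seq_len(n_sec) - 1) * step
    } else {
      secondary_beats[[k]] <- numeric(0)
    }
  }
  structure(
    list(
      main_beats = main_beats,
      secondary_beats = secondary_beats,
      sequence_windows = windows,
      baseline_window = c(0, baseline_s),
      condition = condition
    ),
    class = "cue_schedule"
  )
}

#' @export
print.cue_schedule <- function(x, ...) {
  cat(sprintf("<cue_schedule %s: %d sequences, %d main beats, %d secondary beats>\n",
              x$condition$label, nrow(x$sequence_windows),
              length(unlist(x$main_beats)), length(unlist(x$secondary_beats))))
  invisible(x)
}

#' Flatten a schedule into an event table
#'
#' @param schedule A `cue_schedule`.
#' @return A data.frame with columns `onset_s`, `event_type` (one of main,
#'   secondary, seq_start, seq_end, baseline_start, baseline_end) and
#'   `condition_label`, ordered by onset.
#' @export
schedule_events <- function(schedule) {
  stopifnot(inherits(schedule, "cue_schedule"))
  w <- schedule$sequence_windows
  ev <- rbind(
    data.frame(onset_s = schedule$baseline_window[1], event_type = "baseline_start"),
    data.frame(onset_s = schedule$baseline_window[2], event_type = "baseline_end"),
    data.frame(onset_s = w[, 1], event_type = "seq_start"),
    data.frame(onset_s = w[, 2], event_type = "seq_end"),
    data.frame(onset_s = unlist(schedule$main_beats), event_type = "main"),
    if (length(unlist(schedule$secondary_beats))) {
      data.frame(onset_s = unlist(schedule$secondary_beats), event_type = "secondary")
    }
  )
  ev$condition_label <- schedule$condition$label
  ev <- ev[order(ev$onset_s, ev$event_type), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Write a schedule event table to TSV
#' @param schedule A `cue_schedule`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_schedule_tsv <- function(schedule, path) {
  utils::write.table(schedule_events(schedule), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
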