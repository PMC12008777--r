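# Container and text serialization for multichannel EEG with an attached
# event table.

#' Construct an EEG recording container
#'
#' @param data Channels x samples numeric matrix, in volts.
#' @param sample_rate Sampling rate in Hz.
#' @param channel_names Character vector, one per row of `data`.
#' @param channel_positions n x 3 matrix of unit-sphere electrode positions
#'   (may be NULL for position-free operations).
#' @param events Optional data.frame of events (onset_s, event_type, ...).
#' @param unit Amplitude unit tag, default "V" ("V/m2" after Laplacian).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sample_rate, channel_names,
                          channel_positions = NULL, events = NULL,
                          unit = "V") {
  data <- as.matrix(data)
  if (length(channel_names) != nrow(data)) {
    stop("channel_names must match the number of data rows")
  }
  if (!is.null(channel_positions) &&
      nrow(channel_positions) != nrow(data)) {
    stop("channel_positions must match the number of channels")
  }
  structure(
    list(data = data, sample_rate = sample_rate,
         channel_names = as.character(channel_names),
         channel_positions = channel_positions,
         events = events, unit = unit),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording: %d channels x %d samples @ %g Hz [%s]>\n",
              nrow(x$data), ncol(x$data), x$sample_rate, x$unit))
  invisible(x)
}

#' Time axis of a recording
#' @param rec An `eeg_recording`.
#' @return Sample times in seconds starting at 0.
#' @export
recording_times <- function(rec) {
  (seq_len(ncol(rec$data)) - 1) / rec$sample_rate
}

#' Write a recording as a plain-text bundle
#'
#' Writes `<prefix>_header.json` (rate, channels, positions, unit),
#' `<prefix>_data.tsv` (samples x channels) and, when present,
#' `<prefix>_events.tsv`.
#'
#' @param rec An `eeg_recording`.
#' @param prefix Path prefix for the three files.
#' @return The prefix, invisibly.
#' @export
write_recording_bundle <- function(rec, prefix) {
  header <- list(
    sample_rate = rec$sample_rate,
    channel_names = rec$channel_names,
    unit = rec$unit,
    channel_positions = if (!is.null(rec$channel_positions)) {
      p <- rec$channel_positions
      data.frame(x = p[, 1], y = p[, 2], z = p[, 3])
    }
  )
  jsonlite::write_json(header, paste0(prefix, "_header.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(t(rec$data), paste0(prefix, "_data.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = rec$channel_names)
  if (!is.null(rec$events)) {
    utils::write.table(rec$events, paste0(prefix, "_events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(prefix)
}

#' Read a recording written by [write_recording_bundle()]
#' @param prefix Path prefix used when writing.
#' @return An `eeg_recording`.
#' @export
read_recording_bundle <- function(prefix) {
  header <- jsonlite::read_json(paste0(prefix, "_header.json"),
                                simplifyVector = TRUE)
  dat <- utils::read.table(paste0(prefix, "_data.tsv"), sep = "\t",
                           header = TRUE, check.names = FALSE)
  ev_path <- paste0(prefix, "_events.tsv")
  events <- if (file.exists(ev_path)) {
    utils::read.table(ev_path, sep = "\t", header = TRUE)
  }
  pos <- if (!is.null(header$channel_positions)) {
    unname(as.matrix(as.data.frame(header$channel_positions)))
  }
  eeg_recording(t(as.matrix(dat)), header$sample_rate, header$channel_names,
                channel_positions = pos, events = events, unit = header$unit)
}
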