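#' Normalize an EEG channel label
#'
#' EDF label dialects vary ("EEG F3", "F3-A2", "f3 "). Matching is
#' case-insensitive, drops a leading "EEG" prefix and any "-REF"-style
#' reference suffix, and trims whitespace.
#'
#' @param x character vector of labels.
#' @return normalized upper-case labels.
#' @export
normalize_label <- function(x) {
  x <- toupper(trimws(x))
  x <- sub("^EEG[ _]*", "", x)
  x <- sub("-(A1|A2|M1|M2|REF|LE|AVG)$", "", x)
  trimws(x)
}

#' Locate a channel in a recording by label
#'
#' @param recording a `psg_recording`.
#' @param label channel label (matched after [normalize_label()]).
#' @param required error (naming the label) if not found; otherwise `NA`.
#' @return integer column index into `recording$data`.
#' @export
channel_index <- function(recording, label, required = TRUE) {
  norm <- normalize_label(recording$channel_labels)
  i <- match(normalize_label(label), norm)
  if (is.na(i) && required)
    stop("channel not found in recording: ", label, call. = FALSE)
  i
}

#' Construct a polysomnography recording object
#'
#' @param data numeric matrix, samples x channels, in microvolts.
#' @param channel_labels character vector, one per column.
#' @param rate sampling rate, Hz.
#' @param start_time optional POSIXct start timestamp.
#' @return list of class `psg_recording` with fields `data`,
#'   `channel_labels`, `rate`, `start_time`.
#' @export
psg_recording <- function(data, channel_labels, rate, start_time = NULL) {
  data <- as.matrix(data)
  if (ncol(data) != length(channel_labels))
    stop("data must have one column per channel label", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("sampling rate must be a positive scalar", call. = FALSE)
  colnames(data) <- channel_labels
  structure(list(data = data, channel_labels = channel_labels,
                 rate = rate, start_time = start_time),
            class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat(sprintf("<psg_recording> %d channels x %d samples @ %g Hz (%.1f min)\n",
              ncol(x$data), nrow(x$data), x$rate, nrow(x$data) / x$rate / 60))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording a `psg_recording`.
#' @export
recording_duration <- function(recording) nrow(recording$data) / recording$rate
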