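# Minimal EDF (European Data Format) reader/writer: 16-bit integer samples,
# fixed-width ASCII header, one-second data records. Covers what overnight
# EEG export needs; EDF+ annotation signals are not interpreted.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x, type = "bytes") > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

edf_num <- function(x, width = 8) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  while (nchar(s) > width) {
    # shrink precision until the field fits
    d <- max(1, attr(regexpr("[0-9]+", s), "match.length") - 1)
    s <- formatC(x, format = "g", digits = d, width = 1)
    if (d == 1) break
  }
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16-bit integers against a symmetric physical
#' range chosen per channel from the data, so the round-trip error is at
#' most one quantization step. Signals are padded with zeros to a whole
#' number of one-second data records.
#'
#' @param recording a [psg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  rec <- recording
  ns <- length(rec$channel_labels)
  rate <- rec$rate
  if (abs(rate - round(rate)) > 1e-9)
    stop("write_edf requires an integer sampling rate", call. = FALSE)
  rate <- as.integer(round(rate))
  n <- nrow(rec$data)
  n_rec <- as.integer(ceiling(n / rate))
  pad <- n_rec * rate - n
  phys_max <- vapply(seq_len(ns), function(j) {
    m <- max(abs(range(rec$data[, j], finite = TRUE)), 1)
    ceiling(m * 1.0001)
  }, numeric(1))

  start <- rec$start_time
  if (is.null(start)) start <- as.POSIXct("2000-01-01 23:00:00", tz = "UTC")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)
  wr(edf_pad("0", 8))
  wr(edf_pad("X X X X", 80))
  wr(edf_pad("Startdate X X X X", 80))
  wr(edf_pad(format(start, "%d.%m.%y"), 8))
  wr(edf_pad(format(start, "%H.%M.%S"), 8))
  wr(edf_pad(256L * (ns + 1L), 8))
  wr(edf_pad("", 44))
  wr(edf_pad(n_rec, 8))
  wr(edf_pad("1", 8))
  wr(edf_pad(ns, 4))
  for (j in seq_len(ns)) wr(edf_pad(rec$channel_labels[j], 16))
  for (j in seq_len(ns)) wr(edf_pad("AgAgCl electrode", 80))
  for (j in seq_len(ns)) wr(edf_pad("uV", 8))
  for (j in seq_len(ns)) wr(edf_num(-phys_max[j]))
  for (j in seq_len(ns)) wr(edf_num(phys_max[j]))
  for (j in seq_len(ns)) wr(edf_pad(-32767L, 8))
  for (j in seq_len(ns)) wr(edf_pad(32767L, 8))
  for (j in seq_len(ns)) wr(edf_pad("", 80))
  for (j in seq_len(ns)) wr(edf_pad(rate, 8))
  for (j in seq_len(ns)) wr(edf_pad("", 32))

  scale <- 32767 / phys_max
  dig <- vapply(seq_len(ns), function(j) {
    x <- c(rec$data[, j], numeric(pad))
    as.integer(pmax(-32767L, pmin(32767L, round(x * scale[j]))))
  }, integer(n_rec * rate))
  dig <- matrix(dig, ncol = ns)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * rate + 1L):(r * rate)
    writeBin(as.vector(dig[idx, ]), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' @param path EDF/EDF+ file.
#' @param require_channels character vector of channel labels that must be
#'   present (matched with [normalize_label()]); an error naming the first
#'   missing label is raised otherwise. `NULL` disables the check.
#' @param n_samples optionally trim each channel to this many samples
#'   (EDF stores whole records, so writers pad the tail).
#' @return a [psg_recording()] in microvolts.
#' @export
read_edf <- function(path, require_channels = NULL, n_samples = NULL) {
  if (!file.exists(path)) stop("EDF file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (!identical(version, "0"))
    stop("not an EDF file (bad version field): ", path, call. = FALSE)
  rd(80); rd(80)
  date_s <- rd(8); time_s <- rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header: ", path, call. = FALSE)
  fld <- function(w) vapply(seq_len(ns), function(j) rd(w), character(1))
  labels <- fld(16); fld(80); fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin_ <- as.numeric(fld(8)); dmax_ <- as.numeric(fld(8))
  fld(80)
  nsamp <- as.integer(fld(8))
  fld(32)

  total <- nsamp * n_rec
  data <- matrix(0, nrow = max(total), ncol = ns)
  raw <- readBin(con, "integer", n = sum(nsamp) * n_rec, size = 2L,
                 endian = "little", signed = TRUE)
  off <- 0L
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      seg <- raw[(off + 1L):(off + nsamp[j])]
      data[((r - 1L) * nsamp[j] + 1L):(r * nsamp[j]), j] <- seg
      off <- off + nsamp[j]
    }
  }
  for (j in seq_len(ns)) {
    g <- (pmax_[j] - pmin_[j]) / (dmax_[j] - dmin_[j])
    data[, j] <- (data[, j] - dmin_[j]) * g + pmin_[j]
  }
  if (!is.null(n_samples)) data <- data[seq_len(n_samples), , drop = FALSE]
  rate <- nsamp[1] / rec_dur
  start <- tryCatch(
    as.POSIXct(paste(date_s, time_s), format = "%d.%m.%y %H.%M.%S", tz = "UTC"),
    error = function(e) NULL)
  psg_recording(data, labels, rate, start)
}

#' Read a recording and check the analysis montage
#'
#' Thin wrapper over [read_edf()] that, in strict mode, requires the frontal,
#' central and mastoid channels the pipeline needs (F3, F4, C3, C4, A1, A2).
#'
#' @param path EDF file.
#' @param strict require the full six-channel analysis montage.
#' @inheritParams read_edf
#' @return a [psg_recording()].
#' @export
read_recording <- function(path, strict = TRUE, n_samples = NULL) {
  need <- if (strict) c("F3", "F4", "C3", "C4", "A1", "A2") else NULL
  rec <- read_edf(path, n_samples = n_samples)
  for (lab in need) channel_index(rec, lab, required = TRUE)
  rec
}
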