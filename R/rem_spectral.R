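# REM spectral analysis: Welch power spectral density per 30-s epoch
# (1024-sample Hamming segments, 50% overlap, dB), six-band means for the
# frontal channels, and cross-band standardization of theta.

#' Welch power spectral density of one epoch
#'
#' Segments of `nfft` samples with the given overlap, Hamming-tapered,
#' mean-removed per segment; one-sided periodograms averaged across
#' segments. Power is in uV^2/Hz, also returned as 10*log10 dB.
#'
#' @param x epoch samples (microvolts); must contain at least `nfft`
#'   samples.
#' @param rate sampling rate, Hz.
#' @param nfft segment length in samples.
#' @param overlap fractional overlap between segments.
#' @return data.frame with `freq` (Hz), `power` (uV^2/Hz), `db`.
#' @export
epoch_psd <- function(x, rate, nfft = 1024, overlap = 0.5) {
  n <- length(x)
  if (n < nfft)
    stop(sprintf("epoch too short for PSD: %d samples, need >= %d", n, nfft),
         call. = FALSE)
  step <- max(1L, as.integer(round(nfft * (1 - overlap))))
  starts <- seq(1L, n - nfft + 1L, by = step)
  w <- as.numeric(signal::hamming(nfft))
  u <- sum(w^2)
  nf <- nfft %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nf)]
    P <- (Mod(X)^2) / (rate * u)
    P[2:(nf - 1L)] <- 2 * P[2:(nf - 1L)]   # one-sided, keep DC/Nyquist single
    acc <- acc + P
  }
  P <- acc / length(starts)
  data.frame(freq = (seq_len(nf) - 1L) * rate / nfft, power = P,
             db = 10 * log10(pmax(P, .Machine$double.xmin)))
}

#' Mean band power of a spectrum
#'
#' Mean over frequency bins whose center lies in `[low, high)`.
#'
#' @param psd data.frame from [epoch_psd()].
#' @param band numeric `c(low, high)` in Hz.
#' @param scale `"db"` (default) or `"linear"`.
#' @return scalar mean band power.
#' @export
band_mean <- function(psd, band, scale = "db") {
  sel <- psd$freq >= band[1] & psd$freq < band[2]
  if (!any(sel))
    stop(sprintf("no frequency bins in band [%g, %g) Hz", band[1], band[2]),
         call. = FALSE)
  if (identical(scale, "linear")) mean(psd$power[sel]) else mean(psd$db[sel])
}

#' Band-power table over REM epochs for the frontal channels
#'
#' For every included REM epoch of each requested channel: Welch PSD, then
#' the six band means (delta, theta, alpha, sigma, beta1, beta2) in dB;
#' band means are averaged across epochs. Epochs shorter than one PSD
#' segment are skipped.
#'
#' @param recording preprocessed [psg_recording()].
#' @param mask REM `epoch_mask` (stage set `"REM"`).
#' @param cfg configuration (PSD bands, nfft, overlap, scale).
#' @param channels channels to analyze (frontal pair by default).
#' @return data.frame: `channel`, `band`, `power` (mean dB), `n_epochs`.
#' @export
rem_band_power <- function(recording, mask, cfg = default_config(),
                           channels = c("F3", "F4")) {
  bands <- cfg$bands$psd
  rate <- recording$rate
  nfft <- cfg$psd$nfft
  scale <- cfg$psd$scale
  rows <- list()
  for (lab in channels) {
    j <- channel_index(recording, lab)
    x <- recording$data[, j]
    acc <- setNames(numeric(length(bands)), names(bands))
    used <- 0L
    for (i in which(mask$included)) {
      a <- floor(mask$start_s[i] * rate) + 1L
      b <- min(length(x), ceiling(mask$end_s[i] * rate))
      if (b - a + 1L < nfft) next
      psd <- epoch_psd(x[a:b], rate, nfft = nfft, overlap = cfg$psd$overlap)
      vals <- vapply(bands, function(bd) band_mean(psd, bd, scale), numeric(1))
      acc <- acc + vals
      used <- used + 1L
    }
    if (used == 0L)
      stop("no usable REM epochs for channel ", lab, call. = FALSE)
    rows[[lab]] <- data.frame(channel = lab, band = names(bands),
                              power = unname(acc / used), n_epochs = used,
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Standardize theta power across bands and frontal channels
#'
#' The twelve cells (2 channels x 6 bands) are z-scored against their own
#' mean and (sample) standard deviation; this removes inter-individual
#' differences in overall amplitude while preserving the F3/F4 contrast.
#' The REM theta summary is the mean of the two standardized theta cells.
#'
#' @param table band-power table from [rem_band_power()] with channels F3
#'   and F4 and all six bands.
#' @return list: `theta_z_F3`, `theta_z_F4`, `rem_theta`, and `z_table`
#'   (the full standardized table).
#' @export
standardize_theta <- function(table) {
  if (nrow(table) != 12L)
    stop("standardization expects 12 cells (2 channels x 6 bands), got ",
         nrow(table), call. = FALSE)
  mu <- mean(table$power)
  sdv <- stats::sd(table$power)
  if (!is.finite(sdv) || sdv == 0)
    stop("standardization undefined: zero variance across the 12 cells",
         call. = FALSE)
  z <- (table$power - mu) / sdv
  zt <- table
  zt$z <- z
  pick <- function(ch) z[table$channel == ch & table$band == "theta"]
  t3 <- pick("F3"); t4 <- pick("F4")
  if (length(t3) != 1L || length(t4) != 1L)
    stop("band table must contain one theta cell per frontal channel",
         call. = FALSE)
  list(theta_z_F3 = t3, theta_z_F4 = t4, rem_theta = (t3 + t4) / 2,
       z_table = zt)
}
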