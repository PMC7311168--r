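#' Power spectrum of condition averages over the steady-state window
#'
#' Extracts the analysis window (default 500-3000 ms post-onset, omitting the
#' initial non-stationary interval of the driven response), removes a linear
#' trend per channel, and computes the untapered FFT power spectrum. With the
#' default window of 625 samples at 250 Hz, the resolution is 0.4 Hz and
#' 12 Hz falls exactly on a bin (30 complete cycles), so no taper is needed.
#'
#' @param avg An `averaged_epochs` object (CSD-transformed or not).
#' @param window Length-2 numeric, analysis window in ms relative to onset.
#' @return Object of class `spectrum_table`: `cells` data frame, `power`
#'   (cell x channel x frequency array), `freqs` (Hz), `resolution` (Hz).
#' @export
compute_spectrum <- function(avg, window = c(500, 3000)) {
  fs <- avg$fs
  times <- avg$t0_ms + (seq_len(dim(avg$data)[3]) - 1) * 1000 / fs
  i0 <- which.min(abs(times - window[1]))
  n <- round((window[2] - window[1]) * fs / 1000)
  if (abs(n - (window[2] - window[1]) * fs / 1000) > 1e-9)
    stop("window length times sampling rate must be an integer sample count")
  idx <- i0:(i0 + n - 1)
  if (max(idx) > dim(avg$data)[3] || min(idx) < 1)
    stop("analysis window exceeds the epoch")
  res <- fs / n
  nf <- n %/% 2
  freqs <- (0:nf) * res
  t <- seq_len(n)
  power <- array(0, dim = c(dim(avg$data)[1], dim(avg$data)[2], nf + 1))
  for (i in seq_len(dim(avg$data)[1])) {
    x <- avg$data[i, , idx, drop = TRUE]
    if (dim(avg$data)[2] == 1L) x <- matrix(avg$data[i, 1, idx], nrow = 1)
    # linear detrend per channel
    x <- t(stats::resid(stats::lm.fit(cbind(1, t), t(x))))
    X <- stats::mvfft(t(x))[seq_len(nf + 1), , drop = FALSE]
    power[i, , ] <- t((Mod(X) / n)^2)
  }
  structure(list(cells = avg$cells, power = power, freqs = freqs,
                 resolution = res, window = window),
            class = "spectrum_table")
}

#' Signal-to-noise ratio at the driving frequency
#'
#' SNR = power at `f` divided by the mean power of the six neighbouring bins
#' at f +/- 2, 3, 4 bin widths — the two immediate neighbours (f +/- 1 bin)
#' are excluded because spectral leakage from the signal concentrates there.
#'
#' @param spectrum A `spectrum_table`.
#' @param f Driving frequency in Hz (default 12).
#' @param eps Value added to the noise estimate to guard degenerate noiseless
#'   input; the default 0 raises an error instead.
#' @return Matrix cell x channel of SNR values.
#' @export
snr_at <- function(spectrum, f = 12, eps = 0) {
  res <- spectrum$resolution
  i_f <- which(abs(spectrum$freqs - f) < 1e-9)
  if (!length(i_f))
    stop("frequency ", f, " Hz does not fall on a spectral bin (resolution ",
         res, " Hz)")
  off <- c(-4, -3, -2, 2, 3, 4)
  i_noise <- i_f + off
  if (min(i_noise) < 1 || max(i_noise) > length(spectrum$freqs))
    stop("need at least 4 bins on each side of ", f, " Hz")
  sig <- spectrum$power[, , i_f, drop = FALSE]
  noise <- apply(spectrum$power[, , i_noise, drop = FALSE], c(1, 2), mean)
  if (any(noise == 0) && eps == 0)
    stop("zero noise-bin power (noiseless input); pass eps > 0 to regularize")
  snr <- matrix(sig, dim(spectrum$power)[1], dim(spectrum$power)[2]) /
    (noise + eps)
  snr
}

#' Pool channel SNRs over the occipital cluster
#'
#' Arithmetic mean of the channel-level SNRs across the 8 occipital sensors.
#'
#' @param snr Cell x channel SNR matrix ([snr_at()]), or a named channel
#'   vector.
#' @param montage A `sensor_montage` carrying the cluster definition.
#' @return Numeric vector, one pooled SNR per cell.
#' @export
pool_occipital <- function(snr, montage) {
  idx <- match(montage$occipital_cluster, montage$labels)
  if (anyNA(idx)) stop("occipital cluster channel missing from montage")
  if (is.matrix(snr)) {
    if (max(idx) > ncol(snr)) stop("occipital cluster channel missing from data")
    return(rowMeans(snr[, idx, drop = FALSE]))
  }
  mean(snr[idx])
}

#' Pooled 12 Hz SNRs for one subject's averaged epochs
#'
#' Convenience wrapper: spectrum, per-channel SNR, occipital pooling; returns
#' the subject's long-format rows.
#'
#' @param avg An `averaged_epochs` (after CSD).
#' @param montage A `sensor_montage`.
#' @param subject_id,spai Carried into the output rows.
#' @param f Driving frequency (Hz).
#' @param window Analysis window (ms).
#' @param eps Noise-floor epsilon for [snr_at()].
#' @return `snr_table` rows for this subject.
#' @export
subject_snr_rows <- function(avg, montage, subject_id, spai, f = 12,
                             window = c(500, 3000), eps = 0) {
  spec <- compute_spectrum(avg, window)
  snr <- snr_at(spec, f, eps)
  pooled <- pool_occipital(snr, montage)
  out <- data.frame(subject_id = subject_id,
                    phase = avg$cells$phase,
                    condition = avg$cells$condition,
                    snr = pooled, spai = spai,
                    stringsAsFactors = FALSE)
  class(out) <- c("snr_table", "data.frame")
  out
}
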