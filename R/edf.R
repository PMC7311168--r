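# Minimal EDF (European Data Format) reader/writer for epoched data: one data
# record per trial, all channels at the same sampling rate, 16-bit samples.
# Covers what the pipeline needs for interchange; not a general EDF+ tool.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write an epoch set to an EDF file
#'
#' Stores each trial as one EDF data record (duration = epoch length).
#' Voltages are quantized to 16 bits over a symmetric physical range chosen
#' from the data, so the round trip is lossy only at the quantization step
#' size. Trial metadata (condition, reinforcement) is not representable in
#' plain EDF; write it alongside with [write_trial_meta()].
#'
#' @param epochs An `epoch_set`.
#' @param path Output file path.
#' @param phys_limit Symmetric physical range in microvolts; default expands
#'   to cover the data.
#' @return The path, invisibly.
#' @export
write_edf <- function(epochs, path, phys_limit = NULL) {
  d <- dim(epochs$data)
  n_trial <- d[1]; n_ch <- d[2]; n_samp <- d[3]
  dur <- n_samp / epochs$fs
  lim <- phys_limit %||% max(1, ceiling(max(abs(epochs$data)) * 1.01))
  labels <- epochs$montage$labels %||% paste0("E", seq_len(n_ch))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad("synthetic epochs", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + n_ch), 8),
    edf_pad("", 44),
    edf_pad(n_trial, 8),
    edf_pad(format(dur, digits = 6), 8),
    edf_pad(n_ch, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  field(labels, 16)
  field(rep("EEG", n_ch), 80)
  field(rep("uV", n_ch), 8)
  field(rep(-lim, n_ch), 8)
  field(rep(lim, n_ch), 8)
  field(rep(-32768L, n_ch), 8)
  field(rep(32767L, n_ch), 8)
  field(rep("", n_ch), 80)
  field(rep(n_samp, n_ch), 8)
  field(rep("", n_ch), 32)
  scale <- 65535 / (2 * lim)
  for (tr in seq_len(n_trial)) {
    x <- epochs$data[tr, , , drop = TRUE]
    if (n_ch == 1L) x <- matrix(epochs$data[tr, 1, ], nrow = 1)
    dig <- round((t(x) + lim) * scale - 32768)
    dig <- pmin(32767, pmax(-32768, dig))
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @param montage Optional `sensor_montage` to attach.
#' @param trial_meta Optional trial metadata data frame (e.g. from
#'   [read_trial_meta()]); a placeholder is synthesized otherwise.
#' @return An `epoch_set`.
#' @export
read_edf <- function(path, montage = NULL, trial_meta = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(n_ch), function(i) rd(16), ""))
  rd(80 * n_ch); rd(8 * n_ch)
  pmin <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  rd(80 * n_ch)
  n_samp <- as.integer(vapply(seq_len(n_ch), function(i) rd(8), ""))
  rd(32 * n_ch)
  if (length(unique(n_samp)) != 1L)
    stop("mixed per-channel sampling is not supported")
  ns <- n_samp[1]
  fs <- ns / dur
  data <- array(0, dim = c(n_rec, n_ch, ns))
  for (tr in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = n_ch * ns, size = 2, endian = "little")
    m <- matrix(raw, ns, n_ch)
    for (ch in seq_len(n_ch)) {
      sc <- (pmax[ch] - pmin[ch]) / (dmax[ch] - dmin[ch])
      data[tr, ch, ] <- (m[, ch] - dmin[ch]) * sc + pmin[ch]
    }
  }
  if (is.null(trial_meta))
    trial_meta <- data.frame(phase = NA_character_, condition = NA_character_,
                             reinforced = NA)[rep(1, n_rec), ]
  epoch_set(data, fs = fs, t0_ms = -600, trial_meta = trial_meta,
            montage = montage)
}
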