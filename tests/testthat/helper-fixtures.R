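# Shared fixtures, all generated in code.

fixture_montage <- function(n = 32, cluster = 4) make_montage(n, cluster)

# epoch set with known per-trial content: each trial is a constant matrix of
# `values[tr]` unless a builder function is given
fixture_epochs <- function(n_trial = 4, n_ch = 8, n_samp = 100, fs = 250,
                           build = function(tr, ch, t) 0,
                           montage = NULL, phase = "habituation",
                           condition = NULL) {
  data <- array(0, dim = c(n_trial, n_ch, n_samp))
  t <- (seq_len(n_samp) - 1) / fs
  for (tr in seq_len(n_trial))
    for (ch in seq_len(n_ch))
      data[tr, ch, ] <- build(tr, ch, t)
  condition <- condition %||% rep(c("CS+", "CS-"), length.out = n_trial)
  meta <- data.frame(phase = phase, condition = condition,
                     reinforced = FALSE)
  default_mo <- if (n_ch >= 4) make_montage(n_ch, min(4, n_ch - 1)) else NULL
  epoch_set(data, fs = fs, t0_ms = 0, trial_meta = meta,
            montage = montage %||% default_mo)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# wrap a cell x channel x freq power array as a spectrum table
fixture_spectrum <- function(power, resolution = 0.4) {
  nf <- dim(power)[3]
  structure(list(cells = data.frame(phase = "generalization",
                                    condition = CONDITIONS[seq_len(dim(power)[1])],
                                    n_trials = 1),
                 power = power, freqs = (seq_len(nf) - 1) * resolution,
                 resolution = resolution, window = c(500, 3000)),
            class = "spectrum_table")
}

CONDITIONS <- c("CS+", "GS1", "GS2", "GS3", "GS4", "CS-")

# balanced SNR-like long table with explicit cell means
fixture_long_table <- function(n_subj, conds = CONDITIONS,
                               means = rep(3, length(conds)),
                               subject_sd = 1, resid_sd = 0.5,
                               spai_slope = 0, seed = 1) {
  set.seed(seed)
  spai <- rnorm(n_subj, 67.7, 19.74)
  u <- rnorm(n_subj, 0, subject_sd)
  out <- expand.grid(subject_id = sprintf("S%03d", seq_len(n_subj)),
                     condition = conds, stringsAsFactors = FALSE)
  i <- match(out$subject_id, sprintf("S%03d", seq_len(n_subj)))
  j <- match(out$condition, conds)
  out$snr <- means[j] + u[i] + spai_slope * (spai[i] - mean(spai)) +
    rnorm(nrow(out), 0, resid_sd)
  out$spai <- spai[i]
  out$phase <- if (length(conds) == 6) "generalization" else "acquisition"
  out
}
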