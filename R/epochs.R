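#' Construct an epoch set
#'
#' The unit of data flowing through preprocessing: a trial x channel x sample
#' voltage array with sampling metadata and per-trial condition labels.
#'
#' @param data Numeric array `[trial, channel, sample]`, microvolts.
#' @param fs Sampling rate in Hz.
#' @param t0_ms Time of the first sample relative to stimulus onset (ms).
#' @param trial_meta Data frame with one row per trial; must contain columns
#'   `phase`, `condition`, `reinforced`.
#' @param montage A `sensor_montage` matching the channel dimension.
#' @return Object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, t0_ms, trial_meta, montage) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (nrow(trial_meta) != dim(data)[1])
    stop("trial_meta has ", nrow(trial_meta), " rows but data has ",
         dim(data)[1], " trials")
  if (!is.null(montage) && length(montage$labels) != dim(data)[2])
    stop("montage channel count (", length(montage$labels),
         ") does not match data (", dim(data)[2], ")")
  structure(list(data = data, fs = fs, t0_ms = t0_ms,
                 trial_meta = trial_meta, montage = montage),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Epoch set: %d trials x %d channels x %d samples @ %g Hz, t0 = %g ms\n",
              d[1], d[2], d[3], x$fs, x$t0_ms))
  invisible(x)
}

#' Sample times of an epoch set, in ms relative to stimulus onset
#' @param epochs An `epoch_set`.
#' @return Numeric vector of sample times (ms).
#' @export
epoch_times <- function(epochs) {
  n <- dim(epochs$data)[3]
  epochs$t0_ms + (seq_len(n) - 1) * 1000 / epochs$fs
}

# 1/f^alpha noise via spectral shaping, scaled to unit SD
pink_noise <- function(n, alpha = 1) {
  nf <- n %/% 2
  f <- seq_len(nf)
  mag <- f^(-alpha / 2)
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = mag, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  full[n:(n - nf + 2)] <- Conj(spec[seq_len(nf - 1)])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(x)
  x / s
}

#' Synthesize frequency-tagged EEG epochs for one subject
#'
#' Generates per-trial multichannel epochs spanning -600..+3000 ms at `fs` Hz
#' (900 samples at the default 250 Hz). Each epoch contains a 12 Hz driven
#' sinusoid starting at stimulus onset with a 100 ms cosine on-ramp (avoiding
#' edge ringing; the pre-steady-state interval is discarded by the spectral
#' stage anyway), scaled by the trial condition's amplitude and by a smooth
#' Gaussian spatial profile over the scalp peaking at the occipital pole.
#' Independent 1/f^alpha noise is added per channel, and artifact trials
#' (blocks of saturated channels or high-gradient spikes) can be injected at a
#' configured rate.
#'
#' @param profile One-row subject profile ([sample_subjects()]).
#' @param schedule An `experiment_schedule` (any subset of phases).
#' @param montage A `sensor_montage`.
#' @param pattern Ground-truth tuning shape for [condition_amplitudes()].
#' @param baseline Baseline amplitude of the driven component (microvolts).
#'   The default 0.45 microvolts against 15 microvolt background noise puts
#'   the 15-trial-averaged pooled SNR near the level occipital ssVEP studies
#'   report (about 3.5).
#' @param accent_scale Microvolts of driven-amplitude modulation per SNR-unit
#'   of accentuation (see [condition_amplitudes()]).
#' @param noise_sd Median noise SD per channel in microvolts (0 allowed).
#' @param noise_alpha Spectral exponent of the 1/f^alpha noise.
#' @param channel_noise_cv Log-SD of the per-channel noise level (lognormal
#'   across channels, drawn once per subject). Real electrode noise varies
#'   with impedance and site; perfectly homogeneous channels would make
#'   distribution-based artifact thresholds unrealistically tight.
#' @param spatial_sigma Angular SD (radians) of the occipital signal profile.
#' @param artifact_rate Fraction of trials receiving injected artifacts.
#' @param artifact_channels Range (length-2 integer) of saturated-channel
#'   counts for injected artifact trials.
#' @param fs Sampling rate (Hz).
#' @param flicker_hz Driving frequency (Hz).
#' @param window_ms Epoch span relative to onset, ms (default c(-600, 3000)).
#' @param seed Integer seed.
#' @return An `epoch_set` whose `trial_meta` carries an extra logical column
#'   `artifact_injected`.
#' @export
synthesize_epochs <- function(profile, schedule, montage,
                              pattern = "lateral_inhibition",
                              baseline = 0.45, accent_scale = 0.1,
                              noise_sd = 15, noise_alpha = 1,
                              channel_noise_cv = 0.3,
                              spatial_sigma = 0.7,
                              artifact_rate = 0,
                              artifact_channels = c(21L, 30L),
                              fs = 250, flicker_hz = 12,
                              window_ms = c(-600, 3000),
                              seed = 1L) {
  stopifnot(noise_sd >= 0, noise_alpha >= 0, artifact_rate >= 0,
            artifact_rate <= 1)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  amps <- condition_amplitudes(profile, pattern, baseline, accent_scale)
  n_ch <- length(montage$labels)
  n_trial <- nrow(schedule)
  n_samp <- round((window_ms[2] - window_ms[1]) * fs / 1000)
  t_ms <- window_ms[1] + (seq_len(n_samp) - 1) * 1000 / fs
  t_s <- t_ms / 1000

  # driven waveform: 12 Hz sinusoid from onset with cosine ramp
  env <- ifelse(t_ms < 0, 0, ifelse(t_ms < 100, 0.5 * (1 - cos(pi * t_ms / 100)), 1))
  carrier <- sin(2 * pi * flicker_hz * t_s) * env

  # occipital spatial gain profile
  occ <- montage$positions[montage$occipital_cluster[1], ]
  cosang <- pmin(1, pmax(-1, drop(montage$positions %*% occ)))
  gain <- exp(-(acos(cosang))^2 / (2 * spatial_sigma^2))

  # channel-specific noise levels, fixed across trials
  ch_noise <- noise_sd * exp(stats::rnorm(n_ch, 0, channel_noise_cv))

  data <- array(0, dim = c(n_trial, n_ch, n_samp))
  for (tr in seq_len(n_trial)) {
    a <- amps[[schedule$condition[tr]]]
    sig <- outer(gain * a, carrier)          # channel x sample
    if (noise_sd > 0) {
      for (ch in seq_len(n_ch))
        sig[ch, ] <- sig[ch, ] + ch_noise[ch] * pink_noise(n_samp, noise_alpha)
    }
    data[tr, , ] <- sig
  }

  injected <- rep(FALSE, n_trial)
  if (artifact_rate > 0 && n_trial > 0) {
    n_art <- stats::rbinom(1, n_trial, artifact_rate)
    if (n_art > 0) {
      art_trials <- sample(n_trial, n_art)
      for (tr in art_trials) {
        kind <- sample(c("saturate", "spike"), 1)
        nb <- sample(seq(artifact_channels[1], artifact_channels[2]), 1)
        chs <- sample(n_ch, min(nb, n_ch))
        if (kind == "saturate") {
          data[tr, chs, ] <- 500 * sign(stats::rnorm(length(chs)))
        } else {
          at <- sample(n_samp, 1)
          data[tr, chs, at] <- data[tr, chs, at] + 400
        }
      }
      injected[art_trials] <- TRUE
    }
  }

  meta <- schedule[, c("phase", "condition", "reinforced")]
  meta$artifact_injected <- injected
  epoch_set(data, fs = fs, t0_ms = window_ms[1], trial_meta = meta,
            montage = montage)
}
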