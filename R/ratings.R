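#' Synthesize post-phase subjective ratings
#'
#' Generates valence and arousal (1-9) and US-expectancy (0-100) ratings with
#' a linear generalization gradient: the expected rating decreases linearly
#' from CS+ to CS- with decreasing similarity to the threat cue. Gaussian
#' noise is added and values are clipped to the scale bounds. US expectancy is
#' produced only after acquisition and generalization (it is not collected
#' before conditioning), and only for the conditions shown in that phase.
#'
#' @param profiles Subject profiles ([sample_subjects()]).
#' @param csplus_mean Named list of CS+ expected values per scale.
#' @param slope Named list of per-step linear decrements (rating units per
#'   condition step from CS+ towards CS-).
#' @param noise_sd Named list of rating noise SDs.
#' @param phases Phases to generate ratings for.
#' @param seed Integer seed.
#' @return Data frame with columns `subject_id`, `phase`, `condition`,
#'   `scale`, `value`.
#' @export
synthesize_ratings <- function(profiles,
                               csplus_mean = list(valence = 6.5, arousal = 6.5,
                                                  us_expectancy = 75),
                               slope = list(valence = 0.35, arousal = 0.55,
                                            us_expectancy = 13),
                               noise_sd = list(valence = 1.3, arousal = 1.6,
                                               us_expectancy = 20),
                               phases = PHASES,
                               seed = 1L) {
  stopifnot(all(vapply(slope, is.finite, TRUE)),
            all(vapply(csplus_mean, is.finite, TRUE)))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  bounds <- list(valence = c(1, 9), arousal = c(1, 9), us_expectancy = c(0, 100))
  out <- list()
  for (ph in phases) {
    conds <- if (ph == "generalization") CONDITIONS else c("CS+", "CS-")
    step <- match(conds, CONDITIONS) - 1
    if (ph != "generalization") step <- c(0, 5)[match(conds, c("CS+", "CS-"))]
    scales <- if (ph == "habituation") c("valence", "arousal")
              else c("valence", "arousal", "us_expectancy")
    for (sc in scales) {
      mu <- csplus_mean[[sc]] - slope[[sc]] * step
      # during habituation nothing has been learned yet: flat expectation at
      # the scale midpoint
      if (ph == "habituation") mu <- rep(mean(bounds[[sc]]), length(conds))
      for (i in seq_len(nrow(profiles))) {
        v <- mu + stats::rnorm(length(conds), 0, noise_sd[[sc]])
        v <- pmin(bounds[[sc]][2], pmax(bounds[[sc]][1], v))
        out[[length(out) + 1L]] <- data.frame(
          subject_id = profiles$subject_id[i], phase = ph, condition = conds,
          scale = sc, value = v, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a pooled-SNR table directly (scaled-down generator)
#'
#' Bypasses the EEG synthesis/preprocessing/spectral stages and draws the
#' long-format subject x phase x condition table of pooled 12 Hz SNRs directly
#' from the same ground-truth model the epoch generator plants: each subject's
#' expected SNR is `snr_baseline + accentuation * w(c)/||w||` (plus a CS+
#' conditioning boost during acquisition), with a subject-level random
#' intercept and cell-level residual noise. This is the workhorse for testing
#' the statistics modules at realistic sample sizes where full 129-channel
#' synthesis would be wasteful.
#'
#' @param profiles Subject profiles.
#' @param pattern Ground-truth shape for the generalization phase.
#' @param snr_baseline Expected pooled SNR of an average subject (the level
#'   observed in occipital ssVEP studies is around 3.5).
#' @param subject_sd SD of the subject-level random intercept.
#' @param resid_sd Cell-level residual SD.
#' @param acquisition_boost Added to CS+ cells during acquisition.
#' @param phases Phases to include.
#' @param seed Integer seed.
#' @return Data frame with columns `subject_id`, `phase`, `condition`, `snr`,
#'   `spai` (one row per subject x phase x condition), class `snr_table`.
#' @export
simulate_snr_table <- function(profiles,
                               pattern = "lateral_inhibition",
                               snr_baseline = 3.5,
                               subject_sd = 1.2,
                               resid_sd = 1.0,
                               acquisition_boost = 0.35,
                               phases = PHASES,
                               seed = 1L) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  w <- as_weights(pattern)
  wn <- as.numeric(w) / sqrt(sum(as.numeric(w)^2))
  names(wn) <- CONDITIONS
  n <- nrow(profiles)
  u <- stats::rnorm(n, 0, subject_sd)
  out <- list()
  for (i in seq_len(n)) {
    for (ph in phases) {
      conds <- if (ph == "generalization") CONDITIONS else c("CS+", "CS-")
      mu <- snr_baseline + u[i]
      eff <- if (ph == "generalization") profiles$accentuation[i] * wn[conds] else 0
      if (ph == "acquisition")
        eff <- ifelse(conds == "CS+", acquisition_boost, 0)
      v <- mu + eff + stats::rnorm(length(conds), 0, resid_sd)
      v <- pmax(v, 0.05)  # SNR is a positive ratio
      out[[length(out) + 1L]] <- data.frame(
        subject_id = profiles$subject_id[i], phase = ph, condition = conds,
        snr = v, spai = profiles$spai[i], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("snr_table", "data.frame")
  res
}
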