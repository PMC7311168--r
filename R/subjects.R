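#' Sample synthetic subject profiles
#'
#' Draws a cohort of subjects with a social-anxiety questionnaire score
#' (SPAI-like; truncated normal with mean 67.70 and SD 19.74 by default) and a
#' ground-truth tuning "accentuation": the gain, in pooled-SNR units per unit
#' of normalized contrast weight, with which the subject expresses the planted
#' response pattern. The accentuation is linear in the standardized anxiety
#' score, `gamma0 + gamma1 * z(spai) + noise`, mirroring a linear
#' pattern-by-covariate interaction. Face-to-CS+ assignment alternates across
#' subjects so counts are counterbalanced to within one.
#'
#' @param n Number of subjects (>= 0).
#' @param spai_mean,spai_sd,spai_bounds Truncated-normal parameters of the
#'   anxiety score. The default bounds `c(0, 200)` are wide enough that
#'   truncation shifts the mean by < 0.1% of itself.
#' @param gamma0 Mean accentuation (SNR units per unit normalized weight).
#' @param gamma1 Accentuation slope per SD of the anxiety score.
#' @param accent_sd Residual SD of the accentuation across subjects.
#' @param seed Integer seed.
#' @return Data frame of class `subject_profiles` with columns `subject_id`,
#'   `spai`, `accentuation`, `cs_assignment`.
#' @export
sample_subjects <- function(n,
                            spai_mean = 67.70, spai_sd = 19.74,
                            spai_bounds = c(0, 200),
                            gamma0 = 1.2, gamma1 = 0.7,
                            accent_sd = 0.9,
                            seed = 1L) {
  if (length(n) != 1L || is.na(n) || n < 0)
    stop("n must be a non-negative number")
  stopifnot(spai_sd > 0, spai_bounds[1] < spai_bounds[2])
  n <- as.integer(n)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  spai <- rtruncnorm(n, spai_mean, spai_sd, spai_bounds[1], spai_bounds[2])
  z <- (spai - spai_mean) / spai_sd
  accent <- gamma0 + gamma1 * z + stats::rnorm(n, 0, accent_sd)
  out <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    spai = spai,
    accentuation = accent,
    cs_assignment = rep_len(c(1L, 2L), n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("subject_profiles", "data.frame")
  out
}

# inverse-CDF truncated normal draw
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (n == 0L) return(numeric(0))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

#' Expected 12 Hz amplitudes per condition for one subject
#'
#' Maps a subject's accentuation onto the six condition amplitudes of the
#' driven ssVEP component: `amp(c) = max(0, baseline + accentuation *
#' w(c) / ||w||)`, with `w` the hypothesis weights in canonical order.
#' Dividing by the L2 norm makes the accentuation scale comparable across
#' weight shapes.
#'
#' @param profile One-row subject profile (or a list with `accentuation`).
#' @param pattern Weight specification (see [contrast_weights()]); a shape
#'   name, weights object, or length-6 numeric.
#' @param baseline Baseline amplitude of the driven component, in microvolts
#'   (> 0).
#' @param accent_scale Conversion gain applied to the accentuation (default 1
#'   keeps the canonical formula). The epoch generator passes a microvolt
#'   calibration here, because an accentuation stated in pooled-SNR units
#'   maps onto a much smaller amplitude modulation at the single-trial level.
#' @return Named numeric vector of 6 non-negative amplitudes.
#' @export
condition_amplitudes <- function(profile, pattern = "lateral_inhibition",
                                 baseline = 0.8, accent_scale = 1) {
  stopifnot(baseline > 0)
  w <- as_weights(pattern)
  acc <- if (is.data.frame(profile)) profile$accentuation[1] else profile$accentuation
  stopifnot(is.finite(acc))
  wn <- as.numeric(w) / sqrt(sum(as.numeric(w)^2))
  amps <- pmax(0, baseline + accent_scale * acc * wn)
  names(amps) <- CONDITIONS
  amps
}
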