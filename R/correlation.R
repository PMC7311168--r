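# Default Bayes factor for a Pearson correlation: numerical integration of
# the exact sampling density of r over the population correlation rho under a
# symmetric stretched-beta prior (kappa = 1 reduces to uniform on (-1, 1)).

# Gauss hypergeometric 2F1(a, b; c; z) by series, |z| < 1
hyp2f1 <- function(a, b, cc, z, tol = 1e-12, maxit = 200000L) {
  term <- 1
  s <- 1
  for (j in 0:(maxit - 1)) {
    term <- term * (a + j) * (b + j) / ((cc + j) * (j + 1)) * z
    s <- s + term
    if (abs(term) < tol * abs(s)) return(s)
  }
  warning("hypergeometric series did not converge")
  s
}

# log sampling density of the Pearson correlation r given rho (n pairs)
log_dr_given_rho <- function(r, rho, n) {
  log(n - 2) + lgamma(n - 1) + ((n - 1) / 2) * log1p(-rho^2) +
    ((n - 4) / 2) * log1p(-r^2) - 0.5 * log(2 * pi) - lgamma(n - 0.5) -
    (n - 1.5) * log1p(-rho * r) +
    log(hyp2f1(0.5, 0.5, n - 0.5, (1 + rho * r) / 2))
}

# two-sided default correlation BF: uniform (stretched-beta kappa = 1) prior
correlation_bf <- function(r, n, kappa = 1, grid = 2001) {
  stopifnot(n >= 4, abs(r) < 1)
  rho <- seq(-1 + 1e-6, 1 - 1e-6, length.out = grid)
  # symmetric stretched beta on (-1, 1)
  lprior <- stats::dbeta((rho + 1) / 2, 1 / kappa, 1 / kappa, log = TRUE) -
    log(2)
  lv <- vapply(rho, function(p) log_dr_given_rho(r, p, n), numeric(1)) + lprior
  h <- rho[2] - rho[1]
  # Simpson weights
  wts <- rep(c(2, 4), length.out = grid)
  wts[1] <- wts[grid] <- 1
  lI <- logsumexp(lv + log(wts)) + log(h / 3)
  lI - log_dr_given_rho(r, 0, n)
}

#' Correlation of tuning indices with the anxiety covariate
#'
#' Pearson correlation with the classical t test at n - 2 df, plus a
#' two-sided default Bayes factor for the population correlation rho,
#' obtained by numerically integrating the exact sampling density of r
#' against a symmetric stretched-beta prior on rho (the default
#' `kappa = 1` is uniform on (-1, 1)).
#'
#' @param indices Numeric vector of per-subject tuning indices, or a
#'   `tuning_index_table` data frame (then `spai` is taken from it).
#' @param spai Covariate values (same order), if `indices` is a vector.
#' @param kappa Prior width of the stretched beta.
#' @param grid Number of integration grid points over rho.
#' @return List of class `correlation_result`: `r`, `df`, `t`, `p`,
#'   `bf_rho`, `n`.
#' @export
correlate_with_covariate <- function(indices, spai = NULL, kappa = 1,
                                     grid = 2001) {
  if (is.data.frame(indices)) {
    spai <- indices$spai
    indices <- indices$index
  }
  n <- length(indices)
  if (n < 4) stop("need at least 4 pairs")
  if (length(spai) != n) stop("length mismatch between indices and covariate")
  if (stats::sd(indices) == 0 || stats::sd(spai) == 0)
    stop("zero variance in indices or covariate")
  r <- stats::cor(indices, spai)
  df <- n - 2
  if (1 - r^2 < 1e-12) {
    # perfectly collinear: the likelihood degenerates
    return(structure(list(r = r, df = df, t = sign(r) * Inf, p = 0,
                          bf_rho = Inf, n = n, kappa = kappa),
                     class = "correlation_result"))
  }
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  lbf <- correlation_bf(r, n, kappa, grid)
  structure(list(r = r, df = df, t = tval, p = p, bf_rho = exp(lbf), n = n,
                 kappa = kappa),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r(%d) = %.3f, t = %.2f, p = %.4g, BF10(rho) = %.3g\n",
              x$df, x$r, x$t, x$p, x$bf_rho))
  invisible(x)
}

#' Bootstrap Bayes factor for cross-phase conditioning effects
#'
#' Quantifies how much the acquisition data increase the odds that the CS+
#' minus CS- difference is positive, relative to habituation: each phase's
#' subject-level differences are resampled with replacement `B` times, the
#' group mean difference is computed for each resample, and the odds
#' `P(mean > 0) / P(mean <= 0)` are estimated with Laplace smoothing
#' `(count + 1) / (B - count + 1)` so they stay finite at finite `B`. The
#' Bayes factor is the ratio of acquisition (posterior) over habituation
#' (prior) odds. The whole procedure is repeated `repeats` times and the mean
#' BF is reported with its standard error (also as a percentage). When both
#' phases have the same number of subjects, the same resampling indices are
#' used for both (common random numbers), so identical inputs give BF = 1
#' exactly.
#'
#' @param hab_diffs,acq_diffs Per-subject CS+ minus CS- differences for
#'   habituation and acquisition.
#' @param B Bootstrap resamples per phase (>= 100).
#' @param repeats Repetitions for the error estimate.
#' @param seed Integer seed.
#' @param smooth Use Laplace smoothing (disabling it can yield infinite odds).
#' @return List of class `bootstrap_bf`: `bf` (mean over repeats), `se`,
#'   `error_pct`, `bfs`, `B`, `repeats`.
#' @export
bootstrap_bf <- function(hab_diffs, acq_diffs, B = 100000, repeats = 100,
                         seed = 1L, smooth = TRUE) {
  if (!length(hab_diffs) || !length(acq_diffs)) stop("empty difference vector")
  if (B < 100) stop("B must be at least 100")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  odds <- function(count) {
    if (smooth) (count + 1) / (B - count + 1)
    else count / (B - count)
  }
  nh <- length(hab_diffs); na <- length(acq_diffs)
  shared <- nh == na
  bfs <- numeric(repeats)
  for (rep_i in seq_len(repeats)) {
    if (shared) {
      idx <- sample.int(nh, nh * B, replace = TRUE)
      mh <- colMeans(matrix(hab_diffs[idx], nh, B))
      ma <- colMeans(matrix(acq_diffs[idx], na, B))
    } else {
      mh <- colMeans(matrix(hab_diffs[sample.int(nh, nh * B, replace = TRUE)],
                            nh, B))
      ma <- colMeans(matrix(acq_diffs[sample.int(na, na * B, replace = TRUE)],
                            na, B))
    }
    bfs[rep_i] <- odds(sum(ma > 0)) / odds(sum(mh > 0))
  }
  bf <- mean(bfs)
  se <- stats::sd(bfs) / sqrt(repeats)
  structure(list(bf = bf, se = se, error_pct = 100 * se / bf, bfs = bfs,
                 B = B, repeats = repeats),
            class = "bootstrap_bf")
}

#' @export
print.bootstrap_bf <- function(x, ...) {
  cat(sprintf("Bootstrap BF (posterior/prior odds): %.3f, error = %.2f%% (B = %d, %d repeats)\n",
              x$bf, x$error_pct, x$B, x$repeats))
  invisible(x)
}
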