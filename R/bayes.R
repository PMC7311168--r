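# Weighted-contrast Bayesian linear mixed models with Jeffreys-Zellner-Siow
# priors. The regression coefficients and the error variance are integrated
# analytically; the remaining one or two g parameters (one for the
# standardized fixed-effect block, one for the subject-intercept block) are
# integrated by deterministic quadrature on the log-g scale with a reported
# numerical error, so no MCMC is involved.

# design pieces for one model: standardized fixed columns + subject indicators
jzs_prepare <- function(table, weights, model = c("M1", "M2", "M3"),
                        response = "snr", covariate = "spai") {
  model <- match.arg(model)
  w <- as_weights(weights)
  wn <- as.numeric(w) / sqrt(sum(as.numeric(w)^2))
  names(wn) <- CONDITIONS
  if (!all(table$condition %in% CONDITIONS))
    stop("unknown condition labels in table")
  y <- table[[response]]
  if (anyNA(y)) stop("missing responses are not allowed")
  wv <- wn[table$condition]
  xv <- table[[covariate]] - mean(table[[covariate]])
  std <- function(v) {
    v <- v - mean(v)
    s <- stats::sd(v)
    if (s == 0) stop("degenerate (constant) predictor column")
    v / s
  }
  Wf <- switch(model,
    M1 = cbind(w = std(wv)),
    M2 = cbind(w = std(wv), x = std(xv)),
    M3 = {
      ws <- std(wv); xs <- std(xv)
      cbind(w = ws, x = xs, wx = std(ws * xs))
    })
  subj <- factor(table$subject_id)
  Z <- stats::model.matrix(~ 0 + subj)
  list(y = y, Wf = Wf, Z = Z, N = length(y), pf = ncol(Wf), ns = ncol(Z))
}

# sufficient statistics after projecting out the grand mean (flat prior)
jzs_suffstats <- function(y, W) {
  Wt <- sweep(W, 2, colMeans(W))
  yt <- y - mean(y)
  list(A = crossprod(Wt), b = drop(crossprod(Wt, yt)), s0 = sum(yt^2),
       N = length(y), p = ncol(W))
}

# log p(y | g) with prior precision d_j = 1/g on each column
jzs_log_marg_g <- function(ss, d) {
  M <- ss$A
  diag(M) <- diag(M) + d
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  u <- backsolve(R, ss$b, transpose = TRUE)
  S <- ss$s0 - sum(u^2)
  if (S <= 0) return(-Inf)
  n1 <- (ss$N - 1) / 2
  lgamma(n1) - n1 * log(pi) - 0.5 * log(ss$N) +
    0.5 * sum(log(d)) - sum(log(diag(R))) - n1 * log(S)
}

# log InvGamma(1/2, r^2/2) density
log_dinvgamma_zs <- function(g, r) {
  0.5 * log(r^2 / 2) - lgamma(0.5) - 1.5 * log(g) - r^2 / (2 * g)
}

# deterministic quadrature of the marginal over log g (1 or 2 dims).
# The grid adapts per dimension to the integrand's curvature at the mode
# (Laplace width), so sharply peaked posteriors at large n are still
# resolved. Returns the log integral and an error estimate from grid halving.
jzs_integrate <- function(logf, ndim, nodes = 41, span_sds = 10) {
  opt <- stats::optim(rep(0, ndim), function(t) -logf(t),
                      method = if (ndim == 1) "Brent" else "Nelder-Mead",
                      lower = if (ndim == 1) -30 else -Inf,
                      upper = if (ndim == 1) 30 else Inf,
                      control = list(maxit = 500))
  mode <- opt$par
  f0 <- logf(mode)
  # per-dimension Laplace SD from a second difference
  sds <- vapply(seq_len(ndim), function(i) {
    e <- rep(0, ndim); e[i] <- 0.1
    curv <- (2 * f0 - logf(mode + e) - logf(mode - e)) / 0.1^2
    min(3, max(0.05, 1 / sqrt(max(curv, 1e-4))))
  }, numeric(1))
  span <- pmax(6, span_sds * sds)
  npts <- pmin(501L, pmax(nodes, as.integer(ceiling(2 * span / (sds / 3))) + 1L))
  quad <- function(nv) {
    grids <- lapply(seq_len(ndim), function(i)
      seq(mode[i] - span[i], mode[i] + span[i], length.out = nv[i]))
    if (ndim == 1) {
      lv <- vapply(grids[[1]], logf, numeric(1))
      logsumexp(lv) + log(grids[[1]][2] - grids[[1]][1])
    } else {
      lv <- matrix(0, nv[1], nv[2])
      for (i in seq_len(nv[1])) for (j in seq_len(nv[2]))
        lv[i, j] <- logf(c(grids[[1]][i], grids[[2]][j]))
      logsumexp(lv) + log(grids[[1]][2] - grids[[1]][1]) +
        log(grids[[2]][2] - grids[[2]][1])
    }
  }
  full <- quad(npts)
  half <- quad((npts - 1L) %/% 2L + 1L)
  list(log_integral = full, log_error = abs(full - half))
}

# log marginal likelihood of one model (or the null) by quadrature
jzs_log_marginal <- function(y, Wf, Z, rscale_fixed = 0.5, rscale_random = 1,
                             nodes = 41) {
  null_model <- is.null(Wf) || ncol(Wf) == 0
  W <- if (null_model) Z else cbind(Wf, Z)
  ss <- jzs_suffstats(y, W)
  pf <- if (null_model) 0L else ncol(Wf)
  ns <- ncol(Z)
  if (null_model) {
    logf <- function(t) {
      g <- exp(t)
      jzs_log_marg_g(ss, rep(1 / g, ns)) +
        log_dinvgamma_zs(g, rscale_random) + t
    }
    jzs_integrate(logf, 1L, nodes = max(nodes, 101))
  } else {
    logf <- function(t) {
      gf <- exp(t[1]); gr <- exp(t[2])
      jzs_log_marg_g(ss, c(rep(1 / gf, pf), rep(1 / gr, ns))) +
        log_dinvgamma_zs(gf, rscale_fixed) +
        log_dinvgamma_zs(gr, rscale_random) + sum(t)
    }
    jzs_integrate(logf, 2L, nodes = nodes)
  }
}

#' JZS Bayes factor of a weighted-contrast mixed model against the null
#'
#' Compares `response ~ w(condition) [+ covariate] [+ w(condition) x
#' covariate] + (1 | subject)` against the random-intercept-only null. The
#' hypothesis enters as a single predictor: the centered, L2-normalized
#' contrast weight of each trial's condition. Fixed-effect columns are
#' standardized and carry independent Zellner-Siow priors (Cauchy scale
#' `rscale_fixed` on standardized slopes); the subject-intercept block
#' carries its own g with Cauchy scale `rscale_random`. The Bayes factor is
#' invariant to affine transformations of the weight vector.
#'
#' @param table Long-format table for one phase (columns `subject_id`,
#'   `condition`, response, covariate).
#' @param weights Weight specification (see [contrast_weights()]).
#' @param model `"M1"` (weights only), `"M2"` (+ covariate), `"M3"`
#'   (+ interaction).
#' @param rscale_fixed,rscale_random Cauchy prior scales.
#' @param nodes Quadrature nodes per g dimension.
#' @param response,covariate Column names.
#' @return List of class `jzs_bf`: `bf`, `logbf`, `error` (relative numerical
#'   error of the BF), `model`, `shape`, prior scales.
#' @export
jzs_bf <- function(table, weights, model = c("M1", "M2", "M3"),
                   rscale_fixed = 0.5, rscale_random = 1,
                   nodes = 41, response = "snr", covariate = "spai",
                   .null_marginal = NULL) {
  model <- match.arg(model)
  prep <- jzs_prepare(table, weights, model, response, covariate)
  m1 <- jzs_log_marginal(prep$y, prep$Wf, prep$Z, rscale_fixed, rscale_random,
                         nodes)
  m0 <- .null_marginal %||%
    jzs_log_marginal(prep$y, NULL, prep$Z, rscale_fixed, rscale_random,
                     nodes)
  logbf <- m1$log_integral - m0$log_integral
  if (!is.finite(logbf)) stop("non-finite marginal likelihood")
  err <- m1$log_error + m0$log_error
  if (is.finite(err) && abs(logbf) > 0 && err > 0.05 * abs(logbf))
    warning(sprintf("numerical error (%.3g) exceeds 5%% of |log BF| (%.3g)",
                    err, abs(logbf)))
  structure(list(bf = exp(logbf), logbf = logbf, error = err,
                 model = model,
                 shape = attr(as_weights(weights), "shape"),
                 rscale_fixed = rscale_fixed, rscale_random = rscale_random),
            class = "jzs_bf")
}

#' @export
print.jzs_bf <- function(x, ...) {
  cat(sprintf("JZS BF (%s, %s) vs null: %.4g (log %.3f, num. error %.2g)\n",
              x$shape, x$model, x$bf, x$logbf, x$error))
  invisible(x)
}

#' Monte-Carlo oracle for the JZS marginal likelihood
#'
#' Estimates the same Bayes factor as [jzs_bf()] by brute force: g parameters
#' are drawn from their Zellner-Siow priors and the analytically available
#' conditional marginal likelihood is averaged. Used to validate the
#' quadrature; slow by design.
#'
#' @inheritParams jzs_bf
#' @param ndraws Number of prior draws.
#' @param seed Integer seed.
#' @return List with `bf`, `logbf`, and the two log marginals.
#' @export
jzs_bf_mc <- function(table, weights, model = c("M1", "M2", "M3"),
                      rscale_fixed = 0.5, rscale_random = 1,
                      ndraws = 1e6, seed = 1L,
                      response = "snr", covariate = "spai") {
  model <- match.arg(model)
  prep <- jzs_prepare(table, weights, model, response, covariate)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  rzs <- function(n, r) 1 / stats::rgamma(n, 0.5, rate = r^2 / 2)
  mc_marginal <- function(Wf) {
    null_model <- is.null(Wf)
    W <- if (null_model) prep$Z else cbind(Wf, prep$Z)
    ss <- jzs_suffstats(prep$y, W)
    pf <- if (null_model) 0L else ncol(Wf)
    gf <- if (pf > 0) rzs(ndraws, rscale_fixed) else NULL
    gr <- rzs(ndraws, rscale_random)
    lv <- numeric(ndraws)
    for (i in seq_len(ndraws)) {
      d <- if (pf > 0) c(rep(1 / gf[i], pf), rep(1 / gr[i], prep$ns))
           else rep(1 / gr[i], prep$ns)
      lv[i] <- jzs_log_marg_g(ss, d)
    }
    logsumexp(lv) - log(ndraws)
  }
  m1 <- mc_marginal(prep$Wf)
  m0 <- mc_marginal(NULL)
  list(bf = exp(m1 - m0), logbf = m1 - m0, log_m1 = m1, log_m0 = m0)
}

#' Transitive Bayes factor
#'
#' Relative evidence of model a over model b from their Bayes factors against
#' a common null: `BF(a vs b) = BF(a vs 0) / BF(b vs 0)`.
#'
#' @param bf_a_vs_0,bf_b_vs_0 Positive Bayes factors (numbers or `jzs_bf`).
#' @return Numeric Bayes factor of a over b.
#' @export
transitive_bf <- function(bf_a_vs_0, bf_b_vs_0) {
  a <- if (inherits(bf_a_vs_0, "jzs_bf")) bf_a_vs_0$bf else bf_a_vs_0
  b <- if (inherits(bf_b_vs_0, "jzs_bf")) bf_b_vs_0$bf else bf_b_vs_0
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0)
    stop("Bayes factors must be positive and finite")
  a / b
}

#' Full weighted-contrast Bayesian model comparison
#'
#' Computes, for each hypothesis shape (lateral inhibition, quadratic,
#' linear), the Bayes factors of M1 (weights), M2 (+ covariate) and M3
#' (+ interaction) against the random-intercept-only null, plus the
#' transitive ratios of the lateral-inhibition model over the quadratic and
#' linear shapes for each model tier. Ratios are computed from full-precision
#' BFs, not from rounded values.
#'
#' @param table Long-format SNR table for one phase.
#' @param shapes Shapes to compare.
#' @param models Model tiers.
#' @inheritParams jzs_bf
#' @return List of class `bayes_model_comparison`: `bf` (models x shapes
#'   matrix), `error` (same shape), `vs_quadratic`, `vs_linear` (per model
#'   tier), and the winning shape/model by BF.
#' @export
bayes_model_comparison <- function(table,
                                   shapes = c("lateral_inhibition",
                                              "quadratic", "linear"),
                                   models = c("M1", "M2", "M3"),
                                   rscale_fixed = 0.5, rscale_random = 1,
                                   nodes = 41,
                                   response = "snr", covariate = "spai") {
  bf <- matrix(NA_real_, length(models), length(shapes),
               dimnames = list(models, shapes))
  err <- bf
  # the random-intercept-only null is shared by every comparison
  prep0 <- jzs_prepare(table, "lateral_inhibition", "M1", response, covariate)
  m0 <- jzs_log_marginal(prep0$y, NULL, prep0$Z, rscale_fixed, rscale_random,
                         nodes)
  for (sh in shapes) for (m in models) {
    r <- jzs_bf(table, sh, m, rscale_fixed, rscale_random, nodes,
                response, covariate, .null_marginal = m0)
    bf[m, sh] <- r$bf
    err[m, sh] <- r$error
  }
  vs_q <- if (all(c("lateral_inhibition", "quadratic") %in% shapes))
    bf[, "lateral_inhibition"] / bf[, "quadratic"] else NULL
  vs_l <- if (all(c("lateral_inhibition", "linear") %in% shapes))
    bf[, "lateral_inhibition"] / bf[, "linear"] else NULL
  win <- arrayInd(which.max(bf), dim(bf))
  structure(list(bf = bf, error = err,
                 vs_quadratic = vs_q, vs_linear = vs_l,
                 winner = list(model = models[win[1]], shape = shapes[win[2]])),
            class = "bayes_model_comparison")
}

#' @export
print.bayes_model_comparison <- function(x, ...) {
  cat("Bayes factors vs random-intercept null:\n")
  print(round(x$bf, 3))
  if (!is.null(x$vs_quadratic)) {
    cat("Lateral inhibition vs quadratic:", round(x$vs_quadratic, 3), "\n")
    cat("Lateral inhibition vs linear:   ", round(x$vs_linear, 3), "\n")
  }
  cat("Winner:", x$winner$shape, x$winner$model, "\n")
  invisible(x)
}
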