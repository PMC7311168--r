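# Random-intercept linear mixed model with REML estimation and Satterthwaite
# denominator degrees of freedom. The model class the analysis needs is
# narrow -- y = X beta + u_subject + e with a single random intercept -- so the
# likelihood is computed with per-subject Woodbury identities instead of a
# general sparse solver. On complete balanced designs the Satterthwaite df
# reproduce the Kenward-Roger values (both are exact there).

# sufficient statistics that do not depend on the variance parameters
lmm_suffstats <- function(y, X, subj) {
  subj <- as.factor(subj)
  list(y = y, X = X, subj = subj,
       XtX = crossprod(X), Xty = crossprod(X, y), yty = sum(y^2),
       Sx = rowsum(X, subj), Sy = rowsum(y, subj),
       k = as.numeric(table(subj)), N = length(y), p = ncol(X))
}

# profile REML quantities at vc = (sigma_b^2, sigma^2)
lmm_profile <- function(ss, vc) {
  sb2 <- vc[1]; s2 <- vc[2]
  ci <- sb2 / (s2 + ss$k * sb2)                  # per-subject shrinkage
  XtVX <- (ss$XtX - crossprod(ss$Sx * ci, ss$Sx)) / s2
  XtVy <- (ss$Xty - crossprod(ss$Sx, ci * ss$Sy)) / s2
  ytVy <- (ss$yty - sum(ci * ss$Sy^2)) / s2
  beta <- solve(XtVX, XtVy)
  logdetV <- sum((ss$k - 1) * log(s2) + log(s2 + ss$k * sb2))
  m2ll <- logdetV + determinant(XtVX, logarithm = TRUE)$modulus +
    ytVy - sum(XtVy * beta)
  list(beta = drop(beta), C = solve(XtVX), m2ll = as.numeric(m2ll))
}

# profiled REML criterion in the variance ratio lambda = sb2 / s2 only;
# sigma^2 has a closed form given lambda, so the optimization is 1-d and
# converges to near machine precision
lmm_profile_lambda <- function(ss, lambda) {
  ci <- lambda / (1 + ss$k * lambda)
  XtV0X <- ss$XtX - crossprod(ss$Sx * ci, ss$Sx)
  XtV0y <- ss$Xty - crossprod(ss$Sx, ci * ss$Sy)
  ytV0y <- ss$yty - sum(ci * ss$Sy^2)
  beta <- solve(XtV0X, XtV0y)
  S <- ytV0y - sum(XtV0y * beta)
  s2 <- S / (ss$N - ss$p)
  logdetV0 <- sum(log1p(ss$k * lambda))
  m2ll <- (ss$N - ss$p) * (log(s2) + 1) + logdetV0 +
    as.numeric(determinant(XtV0X, logarithm = TRUE)$modulus)
  list(m2ll = m2ll, s2 = s2, beta = drop(beta), C = s2 * solve(XtV0X))
}

lmm_reml <- function(y, X, subj) {
  ss <- lmm_suffstats(y, X, subj)
  obj <- function(loglam) lmm_profile_lambda(ss, exp(loglam))$m2ll
  opt <- stats::optimize(obj, c(-30, 15), tol = 1e-10)
  # the boundary (no subject variance) may beat the interior optimum
  lam <- exp(opt$minimum)
  if (lmm_profile_lambda(ss, 1e-12)$m2ll < opt$objective) lam <- 1e-12
  prof <- lmm_profile_lambda(ss, lam)
  vc <- c(lam * prof$s2, prof$s2)
  list(ss = ss, vc = vc, beta = prof$beta, C = prof$C, m2ll = prof$m2ll)
}

# observed-information covariance of the REML variance-component estimates
lmm_vc_vcov <- function(fit) {
  ss <- fit$ss; vc <- fit$vc
  f <- function(v) lmm_profile(ss, v)$m2ll
  h <- pmax(vc * 1e-4, 1e-10)
  H <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0); ei[i] <- h[i]; ej[j] <- h[j]
    if (i == j) {
      H[i, i] <- (f(vc + ei) - 2 * f(vc) + f(vc - ei)) / h[i]^2
    } else {
      H[i, j] <- (f(vc + ei + ej) - f(vc + ei - ej) -
                  f(vc - ei + ej) + f(vc - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H <- (H + t(H)) / 2  # symmetrize; H is the Hessian of -2LL
  out <- try(solve(H), silent = TRUE)
  if (inherits(out, "try-error")) matrix(NA_real_, 2, 2) else 2 * out
}

# Satterthwaite df for a single contrast l
satterthwaite_df <- function(fit, l, A = NULL) {
  A <- A %||% lmm_vc_vcov(fit)
  if (anyNA(A)) return(fit$ss$N - fit$ss$p)
  f <- function(v) {
    pr <- lmm_profile(fit$ss, v)
    drop(crossprod(l, pr$C %*% l))
  }
  vc <- fit$vc
  h <- pmax(vc * 1e-4, 1e-10)
  g <- c((f(vc + c(h[1], 0)) - f(vc - c(h[1], 0))) / (2 * h[1]),
         (f(vc + c(0, h[2])) - f(vc - c(0, h[2]))) / (2 * h[2]))
  den <- drop(crossprod(g, A %*% g))
  if (den <= 0) return(fit$ss$N - fit$ss$p)
  2 * f(vc)^2 / den
}

# multi-df F test with Satterthwaite denominator df (eigen-contrast method)
satterthwaite_F <- function(fit, L, A = NULL) {
  A <- A %||% lmm_vc_vcov(fit)
  q <- nrow(L)
  CL <- L %*% fit$C %*% t(L)
  Fstat <- drop(crossprod(L %*% fit$beta, solve(CL, L %*% fit$beta))) / q
  eg <- eigen(CL, symmetric = TRUE)
  Lstar <- diag(1 / sqrt(eg$values), q) %*% t(eg$vectors) %*% L
  nu <- vapply(seq_len(q), function(i) satterthwaite_df(fit, Lstar[i, ], A),
               numeric(1))
  ok <- nu > 2
  if (!any(ok)) {
    df2 <- min(nu)
  } else {
    E <- sum(nu[ok] / (nu[ok] - 2))
    df2 <- if (E > q) 2 * E / (E - q) else min(nu)
  }
  list(F = Fstat, df1 = q, df2 = df2,
       p = stats::pf(Fstat, q, df2, lower.tail = FALSE))
}

#' Fit the condition-by-covariate random-intercept mixed model
#'
#' Fits `response ~ condition * covariate + (1 | subject)` by REML, with the
#' condition factor treatment-coded against a reference level (default CS-)
#' and the covariate mean-centered. Reports the omnibus F test for condition,
#' the t test for the covariate, the F test for the interaction (all with
#' Satterthwaite denominator df, which equal the Kenward-Roger values on the
#' complete balanced designs analyzed here), simple contrasts of every
#' condition against the reference, semi-partial R-squared effect sizes, and
#' the variance components.
#'
#' @param table Long-format data frame; needs columns `subject_id`,
#'   `condition`, the response, and the covariate. Use one phase at a time.
#' @param response Name of the response column (default `"snr"`).
#' @param covariate Name of the subject-level covariate column (default
#'   `"spai"`); mean-centered internally.
#' @param reference Reference condition level for the simple contrasts.
#' @return Object of class `lmm_fit` with elements `coefficients` (data
#'   frame: estimate, se, t, df, p), `tests` (condition / covariate /
#'   interaction), `contrasts`, `varcomp`, `n_subjects`, `N`.
#' @export
fit_lmm <- function(table, response = "snr", covariate = "spai",
                    reference = "CS-") {
  need <- c("subject_id", "condition", response, covariate)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  levs <- intersect(CONDITIONS, unique(table$condition))
  if (!reference %in% levs) stop("reference level ", reference, " absent")
  if (anyNA(table[[response]]) || anyNA(table[[covariate]]))
    stop("missing values in response or covariate are not allowed")
  cond <- factor(table$condition, levels = c(reference, setdiff(levs, reference)))
  tab <- table(table$subject_id, cond)
  if (any(tab != 1))
    stop("each subject must contribute exactly one observation per condition")
  x <- table[[covariate]] - mean(table[[covariate]])
  y <- table[[response]]
  X <- stats::model.matrix(~ cond * x)
  colnames(X) <- sub("^cond", "", colnames(X))
  fit <- lmm_reml(y, X, table$subject_id)
  A <- lmm_vc_vcov(fit)

  p <- ncol(X)
  q <- length(levs) - 1L
  idx_cond <- 1L + seq_len(q)
  idx_x <- 1L + q + 1L
  idx_int <- (1L + q + 1L) + seq_len(q)

  se <- sqrt(diag(fit$C))
  dfs <- vapply(seq_len(p), function(j) {
    l <- numeric(p); l[j] <- 1
    satterthwaite_df(fit, l, A)
  }, numeric(1))
  tval <- fit$beta / se
  coefs <- data.frame(term = colnames(X), estimate = fit$beta, se = se,
                      t = tval, df = dfs,
                      p = 2 * stats::pt(abs(tval), dfs, lower.tail = FALSE),
                      row.names = NULL)

  mkL <- function(idx) {
    L <- matrix(0, length(idx), p)
    L[cbind(seq_along(idx), idx)] <- 1
    L
  }
  cond_test <- satterthwaite_F(fit, mkL(idx_cond), A)
  int_test <- satterthwaite_F(fit, mkL(idx_int), A)
  # covariate main effect = slope averaged over conditions (a pure
  # between-subject contrast; under treatment coding the raw x coefficient
  # would be the reference-level slope instead)
  l_cov <- numeric(p)
  l_cov[idx_x] <- 1
  l_cov[idx_int] <- 1 / (q + 1)
  b_cov <- drop(crossprod(l_cov, fit$beta))
  se_cov <- sqrt(drop(crossprod(l_cov, fit$C %*% l_cov)))
  df_cov <- satterthwaite_df(fit, l_cov, A)
  t_cov <- b_cov / se_cov
  cov_test <- list(t = t_cov, df = df_cov,
                   p = 2 * stats::pt(abs(t_cov), df_cov, lower.tail = FALSE),
                   beta = b_cov, se = se_cov)
  cond_test$r2 <- partial_r2_from_f(cond_test$F, cond_test$df1, cond_test$df2)
  int_test$r2 <- partial_r2_from_f(int_test$F, int_test$df1, int_test$df2)

  contrasts <- coefs[idx_cond, ]
  contrasts$term <- paste(levels(cond)[-1], "vs", reference)

  structure(list(coefficients = coefs,
                 tests = list(condition = cond_test, covariate = cov_test,
                              interaction = int_test),
                 contrasts = contrasts,
                 varcomp = c(subject = fit$vc[1], residual = fit$vc[2]),
                 n_subjects = nlevels(factor(table$subject_id)),
                 N = length(y), reference = reference,
                 fit = fit),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  ct <- x$tests$condition
  it <- x$tests$interaction
  cv <- x$tests$covariate
  cat(sprintf("Random-intercept LMM: %d subjects, N = %d\n", x$n_subjects, x$N))
  cat(sprintf("  Condition:   F(%d, %.1f) = %.3f, p = %.4g, R2 = %.3f\n",
              ct$df1, ct$df2, ct$F, ct$p, ct$r2$r2))
  cat(sprintf("  Covariate:   t(%.1f) = %.3f, p = %.4g, beta = %.3f (SE %.3f)\n",
              cv$df, cv$t, cv$p, cv$beta, cv$se))
  cat(sprintf("  Interaction: F(%d, %.1f) = %.3f, p = %.4g, R2 = %.3f\n",
              it$df1, it$df2, it$F, it$p, it$r2$r2))
  invisible(x)
}

#' Simple contrasts against the reference condition
#'
#' One uncorrected t test per non-reference condition (treatment-coded
#' coefficients of the fitted model, evaluated at the covariate mean).
#'
#' @param fit An `lmm_fit`.
#' @return Data frame with columns `term`, `estimate`, `se`, `t`, `df`, `p`.
#' @export
simple_contrasts <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  fit$contrasts
}

partial_r2_from_f <- function(F, df1, df2, conf = 0.95) {
  r2 <- (df1 / df2 * F) / (1 + df1 / df2 * F)
  # CI by inverting the noncentral-F distribution (ncp <-> R2 mapping)
  alpha <- (1 - conf) / 2
  ncp2r2 <- function(ncp) ncp / (ncp + df1 + df2 + 1)
  safe_pf <- function(q, ncp) {
    v <- suppressWarnings(stats::pf(q, df1, df2, ncp))
    if (is.na(v)) 0 else v  # pf underflows to NaN at extreme ncp
  }
  solve_ncp <- function(target) {
    g <- function(ncp) safe_pf(F, ncp) - target
    if (g(0) <= 0) return(0)
    upper <- max(10, 4 * df1 * F)
    while (g(upper) > 0 && upper < 1e6) upper <- upper * 2
    if (g(upper) > 0) return(upper)
    stats::uniroot(g, c(0, upper))$root
  }
  lo <- solve_ncp(1 - alpha)
  hi <- solve_ncp(alpha)
  list(r2 = r2, ci = c(ncp2r2(lo), ncp2r2(hi)))
}

#' Semi-partial R-squared from a Wald F statistic
#'
#' `R2 = (df1/df2 * F) / (1 + df1/df2 * F)`, with a confidence interval by
#' noncentral-F inversion. This is the standardized-variance variant; the
#' implemented formula is echoed here because published effect sizes computed
#' by other software variants can differ slightly for multi-df effects.
#'
#' @param fit An `lmm_fit`, or a list with `F`, `df1`, `df2`.
#' @param effect Which effect (`"condition"` or `"interaction"`).
#' @param conf Confidence level.
#' @return List with `r2` and `ci`.
#' @export
partial_r2 <- function(fit, effect = "condition", conf = 0.95) {
  if (inherits(fit, "lmm_fit")) {
    ts <- fit$tests[[effect]]
    return(partial_r2_from_f(ts$F, ts$df1, ts$df2, conf))
  }
  partial_r2_from_f(fit$F, fit$df1, fit$df2, conf)
}
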