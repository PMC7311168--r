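test_that("balanced designs reproduce the published df structure", {
  prof <- sample_subjects(67, seed = 3)
  tab <- simulate_snr_table(prof, seed = 4)
  fg <- fit_lmm(tab[tab$phase == "generalization", ])
  expect_equal(fg$tests$condition$df1, 5)
  expect_equal(fg$tests$condition$df2, 325, tolerance = 1e-4)
  expect_equal(fg$tests$covariate$df, 65, tolerance = 1e-4)
  expect_equal(fg$contrasts$df[1], 325, tolerance = 1e-4)
  fa <- fit_lmm(tab[tab$phase == "acquisition", ])
  expect_equal(fa$tests$condition$df1, 1)
  expect_equal(fa$tests$condition$df2, 65, tolerance = 1e-4)
})

test_that("REML estimates agree with lme4 on balanced data", {
  skip_if_not_installed("lme4")
  prof <- sample_subjects(24, seed = 13)
  tab <- simulate_snr_table(prof, seed = 14)
  gen <- tab[tab$phase == "generalization", ]
  fit <- fit_lmm(gen)
  gen$x <- gen$spai - mean(gen$spai)
  gen$cond <- factor(gen$condition,
                     levels = c("CS-", setdiff(CONDITIONS, "CS-")))
  m <- lme4::lmer(snr ~ cond * x + (1 | subject_id), data = gen, REML = TRUE)
  expect_equal(unname(fit$coefficients$estimate), unname(lme4::fixef(m)),
               tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(unname(fit$varcomp["subject"]), vc$vcov[1], tolerance = 1e-4)
  expect_equal(unname(fit$varcomp["residual"]), vc$vcov[2], tolerance = 1e-4)
})

test_that("mixed-model F matches the classical repeated-measures oracle", {
  # on complete balanced data the GLS F for within factors equals the
  # stratified ANOVA F (aov with a subject error stratum)
  prof <- sample_subjects(16, seed = 23)
  tab <- simulate_snr_table(prof, seed = 24)
  gen <- tab[tab$phase == "generalization", ]
  fit <- fit_lmm(gen)
  gen$x <- gen$spai - mean(gen$spai)
  gen$cond <- factor(gen$condition)
  a <- summary(stats::aov(snr ~ cond * x + Error(factor(subject_id)),
                          data = gen))
  within <- a[["Error: Within"]][[1]]
  rn <- trimws(rownames(within))
  expect_equal(fit$tests$condition$F, within[rn == "cond", "F value"],
               tolerance = 1e-8)
  expect_equal(fit$tests$interaction$F, within[rn == "cond:x", "F value"],
               tolerance = 1e-8)
  expect_equal(fit$tests$condition$df2,
               within[rn == "Residuals", "Df"], tolerance = 1e-3)
})

test_that("centering the covariate does not change the condition F test", {
  prof <- sample_subjects(12, seed = 33)
  tab <- simulate_snr_table(prof, seed = 34)
  gen <- tab[tab$phase == "generalization", ]
  f1 <- fit_lmm(gen)
  gen$spai <- gen$spai + 500
  f2 <- fit_lmm(gen)
  expect_equal(f1$tests$condition$F, f2$tests$condition$F, tolerance = 1e-8)
  expect_equal(f1$tests$covariate$t, f2$tests$covariate$t, tolerance = 1e-8)
})

test_that("simple contrasts behave at the degenerate extremes", {
  prof <- sample_subjects(10, seed = 43)
  tab <- simulate_snr_table(prof, seed = 44)
  gen <- tab[tab$phase == "generalization", ]
  # force GS1 identical to CS- within subject
  gen$snr[gen$condition == "GS1"] <-
    gen$snr[gen$condition == "CS-"][match(
      gen$subject_id[gen$condition == "GS1"],
      gen$subject_id[gen$condition == "CS-"])]
  fit <- fit_lmm(gen)
  gs1 <- fit$contrasts[grepl("GS1", fit$contrasts$term), ]
  expect_equal(gs1$estimate, 0, tolerance = 1e-10)
  expect_equal(gs1$p, 1, tolerance = 1e-8)
  # planted separation with almost no noise: p vanishes
  tab2 <- fixture_long_table(12, conds = c("CS+", "CS-"), means = c(5, 3),
                             subject_sd = 0.5, resid_sd = 1e-3, seed = 9)
  fit2 <- fit_lmm(tab2)
  expect_lt(fit2$contrasts$p[1], 1e-10)
})

test_that("missing cells and duplicated cells are rejected", {
  prof <- sample_subjects(6, seed = 53)
  tab <- simulate_snr_table(prof, seed = 54)
  gen <- tab[tab$phase == "generalization", ]
  expect_error(fit_lmm(gen[-1, ]), "exactly one observation")
  expect_error(fit_lmm(rbind(gen, gen[1, ])), "exactly one observation")
  expect_error(fit_lmm(gen, reference = "XX"), "reference")
})

test_that("partial R2 follows the F-statistic identity", {
  expect_equal(ssvepTuning:::partial_r2_from_f(0, 3, 100)$r2, 0)
  # consistency with a published single-df value
  expect_equal(ssvepTuning:::partial_r2_from_f(5.50, 1, 65)$r2, 0.078,
               tolerance = 0.01)
  # the multi-df generalization evaluates to ~0.0496 for F(5,325) = 3.39;
  # software variants that print 0.045 use a different semi-partial form
  expect_equal(ssvepTuning:::partial_r2_from_f(3.39, 5, 325)$r2, 0.0496,
               tolerance = 0.002)
  ci <- ssvepTuning:::partial_r2_from_f(5.50, 1, 65)$ci
  expect_true(ci[1] >= 0 && ci[2] <= 1 && ci[1] < 0.078 && ci[2] > 0.078)
})

test_that("planted interaction slopes are recovered within 2 SE", {
  # parameter recovery: accentuation slope on the standardized covariate
  hits <- 0
  n_rep <- 20
  for (i in seq_len(n_rep)) {
    prof <- sample_subjects(40, gamma0 = 0.8, gamma1 = 0.5, accent_sd = 0.4,
                            seed = 100 + i)
    tab <- simulate_snr_table(prof, seed = 200 + i, phases = "generalization")
    ti <- tuning_index_table(tab)
    # regression of index on standardized spai: slope = gamma1 * ||w||
    z <- (ti$spai - 67.7) / 19.74
    fit <- stats::lm(ti$index ~ z)
    est <- stats::coef(fit)[2]
    se <- sqrt(diag(stats::vcov(fit)))[2]
    truth <- 0.5 * sqrt(sum(as.numeric(contrast_weights("lateral_inhibition"))^2))
    if (abs(est - truth) <= 2 * se) hits <- hits + 1
  }
  expect_gte(hits, 0.75 * n_rep)
})
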