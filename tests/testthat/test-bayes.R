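make_bayes_fixture <- function(n = 8, seed = 10, gamma0 = 1.2, gamma1 = 0.7) {
  prof <- sample_subjects(n, gamma0 = gamma0, gamma1 = gamma1, seed = seed)
  simulate_snr_table(prof, seed = seed + 1, phases = "generalization")
}

test_that("the Bayes factor is invariant to affine weight transformations", {
  tab <- make_bayes_fixture(8)
  w <- as.numeric(contrast_weights("lateral_inhibition"))
  b0 <- jzs_bf(tab, w, "M3")
  b1 <- jzs_bf(tab, 10 * w, "M3")
  b2 <- jzs_bf(tab, w + 3, "M3")     # shifted, re-centered internally
  b3 <- jzs_bf(tab, -0.25 * w + 1, "M3")  # sign flip also leaves BF unchanged
  expect_equal(b1$bf, b0$bf, tolerance = 1e-8)
  expect_equal(b2$bf, b0$bf, tolerance = 1e-8)
  expect_equal(b3$bf, b0$bf, tolerance = 1e-8)
})

test_that("nested Bayes factors are consistent through the common null", {
  tab <- make_bayes_fixture(10, seed = 20)
  bfs <- lapply(c("M1", "M2", "M3"), function(m)
    jzs_bf(tab, "lateral_inhibition", m))
  names(bfs) <- c("M1", "M2", "M3")
  # BF(M3 vs 0) = BF(M3 vs M2) * BF(M2 vs M1) * BF(M1 vs 0)
  chain <- transitive_bf(bfs$M3, bfs$M2) * transitive_bf(bfs$M2, bfs$M1) *
    bfs$M1$bf
  tol <- sum(vapply(bfs, function(b) b$error, numeric(1))) + 1e-6
  expect_equal(log(chain), bfs$M3$logbf, tolerance = max(tol, 1e-5))
})

test_that("transitive BF arithmetic", {
  expect_equal(transitive_bf(10, 2), 5)
  expect_equal(transitive_bf(3.3, 3.3), 1)
  expect_equal(transitive_bf(7, 2) * transitive_bf(2, 7), 1)
  expect_error(transitive_bf(-1, 2), "positive")
  expect_error(transitive_bf(1, 0), "positive")
})

test_that("null data yield median BF below 1", {
  bfs <- vapply(1:12, function(i) {
    prof <- sample_subjects(40, gamma0 = 0, gamma1 = 0, accent_sd = 0,
                            seed = 500 + i)
    tab <- simulate_snr_table(prof, seed = 600 + i, phases = "generalization")
    jzs_bf(tab, "lateral_inhibition", "M1")$bf
  }, numeric(1))
  expect_lt(median(bfs), 1)
})

test_that("quadrature matches the Monte-Carlo oracle on a small fixture", {
  # light version of the acceptance check (the full 1e6-draw oracle runs
  # there); 1e5 draws give ~0.5% MC error on this fixture
  tab <- make_bayes_fixture(6, seed = 30)
  q <- jzs_bf(tab, "lateral_inhibition", "M2")
  mc <- jzs_bf_mc(tab, "lateral_inhibition", "M2", ndraws = 1e5, seed = 31)
  expect_lt(abs(q$bf - mc$bf) / mc$bf, 0.05)
})

test_that("prior scales are configurable and echoed", {
  tab <- make_bayes_fixture(8, seed = 40)
  b1 <- jzs_bf(tab, "linear", "M1", rscale_fixed = 0.5)
  b2 <- jzs_bf(tab, "linear", "M1", rscale_fixed = 1.0)
  expect_false(isTRUE(all.equal(b1$bf, b2$bf)))
  expect_equal(b1$rscale_fixed, 0.5)
  expect_equal(b2$rscale_fixed, 1.0)
})

test_that("model comparison table has the expected structure and winner", {
  prof <- sample_subjects(20, gamma0 = 1.2, gamma1 = 0.7, seed = 50)
  tab <- simulate_snr_table(prof, seed = 51, phases = "generalization")
  cmp <- bayes_model_comparison(tab, nodes = 31)
  expect_equal(dim(cmp$bf), c(3L, 3L))
  expect_true(all(cmp$bf > 0))
  expect_equal(unname(cmp$vs_quadratic),
               unname(cmp$bf[, "lateral_inhibition"] / cmp$bf[, "quadratic"]))
  expect_equal(cmp$winner$shape, "lateral_inhibition")
})
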