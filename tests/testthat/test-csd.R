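test_that("CSD of a spatially constant potential is zero", {
  mo <- make_montage(64, 4)
  v <- matrix(3, 64, 5)
  out <- csd_transform(v, mo)
  expect_lt(max(abs(out)), 1e-8 * 3)
})

test_that("CSD is linear and reference-free", {
  set.seed(31)
  mo <- make_montage(48, 4)
  x <- matrix(rnorm(48 * 3), 48, 3)
  y <- matrix(rnorm(48 * 3), 48, 3)
  a <- 2.3; b <- -1.1
  expect_equal(csd_transform(a * x + b * y, mo),
               a * csd_transform(x, mo) + b * csd_transform(y, mo),
               tolerance = 1e-12)
  shifted <- x + 100
  expect_lt(max(abs(csd_transform(shifted, mo) - csd_transform(x, mo))),
            1e-8 * max(abs(x)))
})

test_that("spherical harmonics are eigenfunctions of the spline Laplacian", {
  mo <- make_montage(256, 8)
  z <- mo$positions[, 3]
  cfg0 <- csd_config(lambda = 0)
  for (case in list(list(v = z, l = 1),
                    list(v = 0.5 * (3 * z^2 - 1), l = 2),
                    list(v = 0.5 * (5 * z^3 - 3 * z), l = 3))) {
    out <- csd_transform(matrix(case$v, ncol = 1), mo, cfg0)
    expected <- case$l * (case$l + 1) * case$v
    keep <- abs(case$v) > 0.1 * max(abs(case$v))
    expect_lt(max(abs(out[keep] - expected[keep]) / abs(expected[keep])), 0.02)
  }
})

test_that("regularization monotonically shrinks high-spatial-frequency output", {
  mo <- make_montage(96, 4)
  z <- mo$positions[, 3]
  # degree-6 Legendre component: high spatial frequency
  v <- (231 * z^6 - 315 * z^4 + 105 * z^2 - 5) / 16
  norms <- vapply(c(0, 0.05, 0.2, 1, 5), function(lam) {
    sum(csd_transform(matrix(v, ncol = 1), mo, csd_config(lambda = lam))^2)
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("degenerate montages are rejected", {
  mo <- make_montage(16, 3)
  mo$positions[2, ] <- mo$positions[1, ]
  expect_error(csd_transform(matrix(1:16, ncol = 1), mo), "duplicate")
  expect_error(csd_config(lambda = -1))
  expect_error(csd_config(m = 1))
})
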