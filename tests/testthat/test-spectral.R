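test_that("default window gives 625 samples, 0.4 Hz bins, 12 Hz on-bin", {
  mo <- fixture_montage(8, 3)
  ep <- fixture_epochs(2, 8, 900, 250,
                       build = function(tr, ch, t) sin(2 * pi * 12 * t),
                       montage = mo)
  ep$t0_ms <- -600
  spec <- compute_spectrum(average_conditions(ep))
  expect_equal(spec$resolution, 0.4)
  i12 <- which(abs(spec$freqs - 12) < 1e-9)
  expect_equal(i12, 31L)  # bin index 30 past DC
  # integer cycles in the window: all non-DC power in the 12 Hz bin
  p <- spec$power[1, 1, -1]
  expect_gt(p[i12 - 1] / sum(p), 0.99)
})

test_that("SNR implements the six-neighbour-bin definition", {
  # flat spectrum -> SNR = 1
  p <- array(2, c(1, 1, 80))
  expect_equal(unname(snr_at(fixture_spectrum(p))[1, 1]), 1)
  # P(f) = 10, six noise bins = 2 -> SNR = 5
  p2 <- array(2, c(1, 1, 80))
  i12 <- 31
  p2[1, 1, i12] <- 10
  p2[1, 1, i12 + c(-1, 1)] <- 99  # immediate neighbours must be ignored
  expect_equal(unname(snr_at(fixture_spectrum(p2))[1, 1]), 5)
  # insufficient margin above the signal bin
  expect_error(snr_at(fixture_spectrum(array(1, c(1, 1, 33)))), "4 bins")
  expect_error(snr_at(fixture_spectrum(array(1, c(1, 1, 80))), 12.9), "bin")
  # degenerate zero noise bins
  p3 <- array(0, c(1, 1, 80)); p3[1, 1, i12] <- 1
  expect_error(snr_at(fixture_spectrum(p3)), "zero")
  expect_equal(unname(snr_at(fixture_spectrum(p3), eps = 0.1)[1, 1]), 10)
})

test_that("SNR is scale invariant and monotone in planted amplitude", {
  mo <- fixture_montage(8, 3)
  sch <- make_schedule(n_per_condition = 2, phases = "habituation", seed = 2)
  prof <- sample_subjects(1, gamma0 = 0, gamma1 = 0, accent_sd = 0, seed = 1)
  ep <- synthesize_epochs(prof, sch, mo, noise_sd = 1, seed = 3)
  avg <- average_conditions(ep)
  s1 <- snr_at(compute_spectrum(avg))
  avg$data <- avg$data * 37
  expect_equal(snr_at(compute_spectrum(avg)), s1, tolerance = 1e-9)
  snrs <- vapply(c(0.3, 0.6, 1.2, 2.4), function(a) {
    e <- synthesize_epochs(prof, sch, mo, baseline = a, noise_sd = 1, seed = 3)
    mean(subject_snr_rows(average_conditions(e), mo, "s", 0)$snr)
  }, numeric(1))
  expect_true(all(diff(snrs) > 0))
})

test_that("white-noise SNR matches the chi-square ratio expectation", {
  # oracle: signal bin and the 6 noise bins are iid Exp; E[X / mean(Y)] by
  # direct Monte Carlo
  set.seed(77)
  nsim <- 200000
  oracle <- mean(rexp(nsim) / rowMeans(matrix(rexp(6 * nsim), ncol = 6)))
  # pipeline: white-noise epochs through spectrum + snr
  mo <- fixture_montage(4, 2)
  snrs <- c()
  set.seed(88)
  for (i in 1:60) {
    d <- array(rnorm(2 * 4 * 900), c(2, 4, 900))
    ep <- epoch_set(d, 250, -600,
                    data.frame(phase = "habituation",
                               condition = c("CS+", "CS-"),
                               reinforced = FALSE), mo)
    snrs <- c(snrs, as.numeric(snr_at(compute_spectrum(average_conditions(ep)))))
  }
  se <- sd(snrs) / sqrt(length(snrs))
  expect_lt(abs(mean(snrs) - oracle), 3 * se + 0.02)
})

test_that("occipital pooling averages the cluster channels", {
  mo <- fixture_montage(10, 8)
  snr <- matrix(0, 2, 10)
  idx <- match(mo$occipital_cluster, mo$labels)
  snr[1, idx] <- 3
  snr[2, idx] <- 1:8
  expect_equal(pool_occipital(snr, mo), c(3, 4.5))
  # permuting non-cluster channels leaves the pooled value unchanged
  other <- setdiff(seq_len(10), idx)
  snr2 <- snr
  snr2[, other] <- snr[, rev(other)]
  expect_equal(pool_occipital(snr2, mo), pool_occipital(snr, mo))
  mo_bad <- mo
  mo_bad$occipital_cluster <- c(mo$occipital_cluster, "E99")
  expect_error(pool_occipital(snr, mo_bad), "missing")
})
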