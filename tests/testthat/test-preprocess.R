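test_that("low-pass filter has the designed magnitude response", {
  fs <- 250; n <- 1000
  t <- (seq_len(n) - 1) / fs
  mk <- function(f) fixture_epochs(2, 1, n, fs,
                                   build = function(tr, ch, tt) sin(2 * pi * f * tt))
  amp_ratio <- function(f) {
    ep <- mk(f)
    out <- lowpass_filter(ep, 40)
    # compare RMS in the interior (avoid FFT wrap-around at the edges)
    idx <- 100:900
    sqrt(mean(out$data[1, 1, idx]^2) / mean(ep$data[1, 1, idx]^2))
  }
  dc <- fixture_epochs(2, 1, n, fs, build = function(tr, ch, tt) 5)
  expect_equal(lowpass_filter(dc, 40)$data, dc$data, tolerance = 1e-10)
  expect_gt(amp_ratio(12), 0.99)       # < 1% attenuation at the tag frequency
  expect_lt(amp_ratio(60), 0.10)       # > 90% attenuation at mains range
  expect_error(lowpass_filter(dc, 130), "Nyquist")
})

test_that("filtering and interpolation are linear operations", {
  set.seed(21)
  mo <- fixture_montage(12, 3)
  mk <- function() {
    d <- array(rnorm(2 * 12 * 200), c(2, 12, 200))
    epoch_set(d, 250, 0, data.frame(phase = "habituation",
                                    condition = c("CS+", "CS-"),
                                    reinforced = FALSE), mo)
  }
  x <- mk(); y <- mk()
  a <- 1.7; b <- -0.6
  z <- x; z$data <- a * x$data + b * y$data
  expect_equal(lowpass_filter(z)$data,
               a * lowpass_filter(x)$data + b * lowpass_filter(y)$data,
               tolerance = 1e-10)
  flags <- matrix(FALSE, 2, 12); flags[1, 3] <- TRUE
  rep_f <- structure(list(flags = flags, rejected = c(FALSE, FALSE)),
                     class = "artifact_report")
  iz <- interpolate_channels(z, rep_f, mo)
  ix <- interpolate_channels(x, rep_f, mo)
  iy <- interpolate_channels(y, rep_f, mo)
  expect_equal(iz$data, a * ix$data + b * iy$data, tolerance = 1e-8)
})

test_that("artifact detection implements the bad-channel-count rule", {
  set.seed(5)
  n_ch <- 129
  mo <- make_montage(n_ch, 8)
  base <- array(0, c(12, n_ch, 120))
  sds <- runif(n_ch, 8, 20)
  for (ch in seq_len(n_ch)) base[, ch, ] <- rnorm(12 * 120, sd = sds[ch])
  mk <- function(n_sat) {
    d <- base
    if (n_sat > 0) d[1, seq_len(n_sat), ] <- 500
    epoch_set(d, 250, 0,
              data.frame(phase = "habituation",
                         condition = rep(c("CS+", "CS-"), 6),
                         reinforced = FALSE), mo)
  }
  r21 <- detect_artifacts(mk(21), max_bad = 20)
  expect_true(r21$rejected[1])
  expect_false(any(r21$rejected[-1]))
  r20 <- detect_artifacts(mk(20), max_bad = 20)
  expect_false(r20$rejected[1])
  expect_equal(sum(r20$flags[1, seq_len(20)]), 20)
  # all-constant data yields no flags
  const <- mk(0); const$data[] <- 3
  expect_equal(sum(detect_artifacts(const)$flags), 0)
})

test_that("rejection depends on flag counts, not condition labels", {
  set.seed(6)
  mo <- fixture_montage(16, 3)
  d <- array(rnorm(10 * 16 * 100), c(10, 16, 100))
  ep1 <- epoch_set(d, 250, 0, data.frame(phase = "habituation",
                                         condition = rep("CS+", 10),
                                         reinforced = FALSE), mo)
  ep2 <- epoch_set(d, 250, 0, data.frame(phase = "habituation",
                                         condition = rep(c("CS+", "CS-"), 5),
                                         reinforced = FALSE), mo)
  expect_identical(detect_artifacts(ep1)$flags, detect_artifacts(ep2)$flags)
  expect_identical(detect_artifacts(ep1)$rejected, detect_artifacts(ep2)$rejected)
})

test_that("spline interpolation recovers smooth fields", {
  mo <- make_montage(64, 4)
  pos <- mo$positions
  # constant potential: interpolation returns the constant
  v <- matrix(5, 64, 10)
  flags <- matrix(FALSE, 1, 64); flags[1, 7] <- TRUE
  ep <- epoch_set(array(v, c(1, 64, 10)), 250, 0,
                  data.frame(phase = "habituation", condition = "CS+",
                             reinforced = FALSE)[1, ], mo)
  # need >= 2 trials only for detection, not interpolation
  rep_f <- structure(list(flags = flags, rejected = FALSE),
                     class = "artifact_report")
  out <- interpolate_channels(ep, rep_f, mo)
  expect_equal(out$data[1, 7, ], rep(5, 10), tolerance = 1e-6)
  # unflagged channels are untouched bit-for-bit
  expect_identical(out$data[1, -7, ], ep$data[1, -7, ])
  # degree-1 spherical harmonic: analytic field recovered at the sensor
  vz <- pos[, 3]
  ep2 <- epoch_set(array(vz, c(1, 64, 1)), 250, 0, ep$trial_meta, mo)
  out2 <- interpolate_channels(ep2, rep_f, mo)
  expect_lt(abs(out2$data[1, 7, 1] - vz[7]) / max(abs(vz)), 1e-3)
  # too few good channels
  flags_all <- matrix(TRUE, 1, 64); flags_all[1, 1:3] <- FALSE
  rep_bad <- structure(list(flags = flags_all, rejected = FALSE),
                       class = "artifact_report")
  expect_error(interpolate_channels(ep, rep_bad, mo), "fewer than 4")
})

test_that("condition averaging uses retained trials only", {
  mo <- fixture_montage(8, 3)
  d <- array(0, c(4, 8, 50))
  d[1, , ] <- 2; d[2, , ] <- 2; d[3, , ] <- 7; d[4, , ] <- -7
  ep <- epoch_set(d, 250, 0,
                  data.frame(phase = "habituation",
                             condition = c("CS+", "CS+", "CS-", "CS-"),
                             reinforced = FALSE), mo)
  avg <- average_conditions(ep)
  expect_equal(avg$data[avg$cells$condition == "CS+", 1, 1], 2)
  expect_equal(avg$data[avg$cells$condition == "CS-", 1, 1], 0)
  expect_equal(avg$cells$n_trials, c(2L, 2L))
  rep_f <- structure(list(flags = matrix(FALSE, 4, 8),
                          rejected = c(FALSE, FALSE, TRUE, TRUE)),
                     class = "artifact_report")
  expect_error(average_conditions(ep, rep_f), "CS-")
  # reinforced exclusion
  ep$trial_meta$reinforced <- c(TRUE, FALSE, FALSE, FALSE)
  avg2 <- average_conditions(ep, exclude_reinforced = TRUE)
  expect_equal(avg2$cells$n_trials[avg2$cells$condition == "CS+"], 1L)
})
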