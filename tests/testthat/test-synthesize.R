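test_that("epochs have the specified geometry and a 12 Hz driven component", {
  mo <- fixture_montage(16, 3)
  prof <- sample_subjects(1, seed = 1)
  sch <- make_schedule(n_per_condition = 2, phases = "habituation", seed = 2)
  ep <- synthesize_epochs(prof, sch, mo, noise_sd = 0, seed = 3)
  expect_equal(dim(ep$data), c(4L, 16L, 900L))
  expect_equal(epoch_times(ep)[1], -600)
  # noiseless: post-onset spectral power concentrates at 12 Hz everywhere
  avg <- average_conditions(ep)
  spec <- compute_spectrum(avg)
  for (ch in seq_len(16)) {
    p <- spec$power[1, ch, -1]
    if (sum(p) == 0) next  # far-field channels with ~zero gain
    expect_gt(p[which(abs(spec$freqs[-1] - 12) < 1e-9)] / sum(p), 0.99)
  }
})

test_that("pooled SNR scales approximately with amplitude squared", {
  # at weak noise the 12 Hz bin is signal-dominated, so doubling the driven
  # amplitude should roughly quadruple the pooled SNR
  mo <- fixture_montage(16, 3)
  sch <- make_schedule(n_per_condition = 3, phases = "habituation", seed = 2)
  snr_for <- function(baseline) {
    prof <- sample_subjects(1, gamma0 = 0, gamma1 = 0, accent_sd = 0, seed = 1)
    ep <- synthesize_epochs(prof, sch, mo, baseline = baseline, noise_sd = 0.5,
                            seed = 9)
    mean(subject_snr_rows(average_conditions(ep), mo, "S001", 0)$snr)
  }
  r <- snr_for(2) / snr_for(1)
  expect_gt(r, 3.2)
  expect_lt(r, 4.8)
})

test_that("zero accentuation yields flat expected SNRs across conditions", {
  # the noise bins of a single averaged spectrum are chi-square with few
  # degrees of freedom, so per-cell SNR is noisy; average over seeds and
  # compare the per-condition means
  mo <- fixture_montage(16, 8)
  prof <- sample_subjects(1, gamma0 = 0, gamma1 = 0, accent_sd = 0, seed = 1)
  sch <- make_schedule(n_per_condition = 5, phases = "generalization",
                       seed = 4)
  acc <- matrix(0, 8, 6)
  for (s in 1:8) {
    ep <- synthesize_epochs(prof, sch, mo, noise_sd = 1, seed = 40 + s)
    rows <- subject_snr_rows(average_conditions(ep), mo, "S001", 0)
    acc[s, ] <- rows$snr[match(CONDITIONS, rows$condition)]
  }
  m <- colMeans(acc)
  # a planted pattern at default accentuation would give a ratio above ~2
  expect_lt(max(m) / min(m), 1.4)
})

test_that("artifact injection and channel-count mismatch are handled", {
  mo <- fixture_montage(16, 3)
  prof <- sample_subjects(1, seed = 1)
  sch <- make_schedule(n_per_condition = 10, phases = "habituation", seed = 2)
  ep <- synthesize_epochs(prof, sch, mo, artifact_rate = 0.3,
                          artifact_channels = c(5, 8), seed = 6)
  expect_gt(sum(ep$trial_meta$artifact_injected), 0)
  expect_gte(max(abs(ep$data)), 400)
  mo8 <- fixture_montage(8, 3)
  bad <- ep
  expect_error(epoch_set(ep$data, ep$fs, ep$t0_ms, ep$trial_meta, mo8),
               "montage channel count")
})

test_that("ratings respect scale bounds and the linear gradient", {
  prof <- sample_subjects(3, seed = 1)
  r <- synthesize_ratings(prof, noise_sd = list(valence = 0, arousal = 0,
                                                us_expectancy = 0), seed = 2)
  gen <- r[r$phase == "generalization" & r$scale == "valence" &
           r$subject_id == "S001", ]
  v <- gen$value[match(CONDITIONS, gen$condition)]
  expect_equal(diff(v), rep(-0.35, 5), tolerance = 1e-12)
  expect_false(any(r$scale == "us_expectancy" & r$phase == "habituation"))
  # noisy ratings stay clipped to their scales
  rn <- synthesize_ratings(prof, noise_sd = list(valence = 50, arousal = 50,
                                                 us_expectancy = 500), seed = 3)
  expect_true(all(rn$value[rn$scale != "us_expectancy"] >= 1 &
                  rn$value[rn$scale != "us_expectancy"] <= 9))
  expect_true(all(rn$value[rn$scale == "us_expectancy"] >= 0 &
                  rn$value[rn$scale == "us_expectancy"] <= 100))
})
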