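# Synthetic-data generators: determinism, noise statistics, end-to-end
# recovery through the analysis stages.

test_that("IR sequences are pure functions of (config, seed)", {
  fld <- function(x, y, t) 25 + 10 * exp(-(x^2 + y^2) / 8)
  cfg <- ir_synthetic_config(fld, frame_size = c(24, 32), noise_sd = 0.2,
                             duration_s = 0.2, seed = 11)
  a <- gen_ir_sequence(cfg)
  b <- gen_ir_sequence(cfg)
  expect_identical(a, b)
  cfg2 <- cfg; cfg2$seed <- 12
  expect_false(identical(gen_ir_sequence(cfg2), a))
})

test_that("noiseless frames equal the resampled field exactly", {
  fld <- function(x, y, t) 25 + 0.5 * x - 0.25 * y + t
  cfg <- ir_synthetic_config(fld, frame_size = c(16, 16), noise_sd = 0,
                             duration_s = 0.1, pitch_mm = 0.5, seed = 1)
  frames <- gen_ir_sequence(cfg)
  xs <- (seq_len(16) - 8.5) * 0.5
  ys <- (seq_len(16) - 8.5) * 0.5
  expect_equal(frames[[1]]$values, outer(ys, xs, function(Y, X) fld(X, Y, 0)))
  expect_equal(frames[[2]]$time_s, 1 / 30)
})

test_that("per-pixel noise sd matches the configured level", {
  fld <- function(x, y, t) 30    # static field
  cfg <- ir_synthetic_config(fld, frame_size = c(8, 8), noise_sd = 0.2,
                             duration_s = 10, seed = 5)   # 300 frames
  frames <- gen_ir_sequence(cfg)
  stack <- sapply(frames, function(f) f$values[3, 4])
  expect_length(stack, 300)
  expect_gt(sd(stack), 0.18)
  expect_lt(sd(stack), 0.22)
})

test_that("artifact blobs perturb the field locally", {
  fld <- function(x, y, t) 25
  art <- data.frame(x_mm = 0, y_mm = 0, radius_mm = 1, amplitude_C = 5)
  cfg <- ir_synthetic_config(fld, frame_size = c(21, 21), noise_sd = 0,
                             duration_s = 1 / 30, pitch_mm = 0.5,
                             artifacts = art, seed = 1)
  fr <- gen_ir_sequence(cfg)[[1]]
  expect_equal(fr$values[11, 11], 30)          # centre pixel +5
  expect_lt(abs(fr$values[1, 1] - 25), 0.01)   # far corner ~untouched
})

test_that("synthetic spectra expose ground truth and respect the seed", {
  cfg <- raman_synthetic_config(noise_sd = 10, seed = 21)
  a <- gen_raman_spectrum(cfg)
  b <- gen_raman_spectrum(cfg)
  expect_identical(a$spectrum$intensity, b$spectrum$intensity)
  expect_equal(a$truth$center, c(1247, 1325))
  # baseline-only spectrum: subtract_baseline leaves ~nothing
  base_only <- raman_synthetic_config(
    peaks = data.frame(center = numeric(), height = numeric(),
                       fwhm = numeric(), eta = numeric()),
    baseline = c(100, -30, 40), noise_sd = 0)
  g <- gen_raman_spectrum(base_only)
  out <- subtract_baseline(g$spectrum, degree = 3)
  expect_lt(max(abs(out$spectrum$intensity)), 1e-6 * 100)
})

test_that("noiseless default pair reproduces the 2.29 band ratio", {
  g <- gen_raman_spectrum(raman_synthetic_config())
  pk <- fit_peaks(g$spectrum, c(1247, 1325))
  expect_equal(band_ratio(pk)$ratio, 2.29, tolerance = 0.01)
})

test_that("strength draws respect the group structure", {
  # sd = 0: every sample equals its group mean
  cfg0 <- strength_synthetic_config(sds = rep(0, 5),
                                    failure_prob = rep(0, 5), seed = 2)
  s0 <- gen_strength_samples(cfg0)
  gs <- group_stats(s0)
  expect_equal(gs$mean, cfg0$means, tolerance = 1e-12)
  expect_equal(gs$max, gs$min)
  # large n: sample means within 2 % of the configured means
  cfgN <- strength_synthetic_config(groups = c(20, 25),
                                    means = c(0.24, 0.32),
                                    sds = c(0.025, 0.022),
                                    failure_prob = 0, n = 10000, seed = 9)
  gsN <- group_stats(gen_strength_samples(cfgN))
  expect_true(all(abs(gsN$mean - c(0.24, 0.32)) / c(0.24, 0.32) < 0.02))
  # fixed seed: retained count after filtering is reproducible
  cfgF <- strength_synthetic_config(failure_prob = c(0, 0, 0, 0, 0.6),
                                    seed = 4)
  n1 <- nrow(filter_samples(gen_strength_samples(cfgF)))
  n2 <- nrow(filter_samples(gen_strength_samples(cfgF)))
  expect_identical(n1, n2)
  # group means recovered within 2 sd / sqrt(n) at the default n
  cfgD <- strength_synthetic_config(failure_prob = rep(0, 5), seed = 6)
  gsD <- group_stats(gen_strength_samples(cfgD))
  expect_true(all(abs(gsD$mean - cfgD$means) <=
                    2 * cfgD$sds / sqrt(cfgD$n) + 1e-12))
})

test_that("IR generator resamples a simulated field", {
  cfg <- simulation_config(geometry = tiny_geometry(),
                           drive = drive_waveform(8), t_end = 1,
                           dt = 0.05, checkpoint_times = 1, tol = 1e-8)
  sim <- run_simulation(cfg)
  ir <- ir_synthetic_config(sim, frame_size = c(12, 24), pitch_mm = 0.25,
                            noise_sd = 0, duration_s = 1 / 30,
                            t_start_s = 1, seed = 1)
  fr <- gen_ir_sequence(ir)[[1]]
  # centre pixels sit over the weld: hotter than the corners
  expect_gt(fr$values[6, 12], fr$values[1, 1])
  expect_true(all(is.finite(fr$values)))
})
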