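# Raman pipeline: smoothing, baseline, cropping, pseudo-Voigt calibration
# and band ratios.

test_that("Savitzky-Golay smoothing preserves what it must", {
  nu <- seq(800, 1000, 1)
  const <- raman_spectrum(nu, rep(5, length(nu)))
  expect_equal(smooth_spectrum(const, 11, 3)$intensity, const$intensity)
  # window 3 / order 2 is the interpolating case: identity
  set.seed(1)
  any_sp <- raman_spectrum(nu, rnorm(length(nu)))
  expect_equal(smooth_spectrum(any_sp, 3, 2)$intensity, any_sp$intensity,
               tolerance = 1e-10)
  # variance reduction: white noise sd 1 -> output sd < 0.6
  set.seed(2)
  noise <- raman_spectrum(seq(800, 2000, 1), rnorm(1201))
  sm <- smooth_spectrum(noise, 11, 3)
  expect_lt(sd(sm$intensity[50:1150]), 0.6)
  expect_error(smooth_spectrum(const, 4, 2), "odd")
  expect_error(smooth_spectrum(const, 11, 11), "order")
  expect_error(smooth_spectrum(raman_spectrum(1:5, 1:5), 7), "larger")
})

test_that("polynomial baseline removal recovers polynomials and peaks", {
  nu <- seq(800, 2000, 1)
  u <- (nu - 800) / 1200
  base <- 100 + 50 * u - 80 * u^2
  out <- subtract_baseline(raman_spectrum(nu, base), degree = 2)
  expect_lt(max(abs(out$spectrum$intensity)), 1e-6 * max(abs(base)))
  # baseline + one narrow peak: height recovered within 2 %
  peak <- pseudo_voigt(nu, 1247, 1000, 20, 0.5)
  out2 <- subtract_baseline(raman_spectrum(nu, base + peak), degree = 5)
  h <- max(out2$spectrum$intensity[abs(nu - 1247) < 5])
  expect_lt(abs(h - 1000) / 1000, 0.02)
  # degree 0 on a constant spectrum zeroes it
  out3 <- subtract_baseline(raman_spectrum(nu, rep(7, length(nu))),
                            degree = 0)
  expect_equal(out3$spectrum$intensity, rep(0, length(nu)),
               tolerance = 1e-10)
})

test_that("cropping respects the fingerprint window", {
  nu <- seq(400, 2400, 1)
  sp <- raman_spectrum(nu, seq_along(nu))
  cr <- crop_spectrum(sp, 800, 2000)
  expect_equal(range(cr$wavenumber), c(800, 2000))
  full <- crop_spectrum(sp, min(nu), max(nu))
  expect_equal(full$wavenumber, sp$wavenumber)
  expect_error(crop_spectrum(crop_spectrum(sp, 800, 2000), 3000, 4000),
               "empty")
  expect_error(crop_spectrum(sp, 2000, 800), "lo")
})

test_that("pseudo-Voigt fits recover noiseless parameters to 0.1%", {
  g <- gen_raman_spectrum(raman_synthetic_config(
    peaks = data.frame(center = 1247, height = 1000, fwhm = 40, eta = 0.5)))
  p <- fit_peaks(g$spectrum, 1247)[[1]]
  expect_lt(abs(p$center - 1247) / 1247, 1e-3)
  expect_lt(abs(p$height - 1000) / 1000, 1e-3)
  expect_lt(abs(p$fwhm - 40) / 40, 1e-3)
  expect_lt(abs(p$eta - 0.5), 1e-3)
  # two overlapping peaks 78 1/cm apart: centres within 1 1/cm
  g2 <- gen_raman_spectrum(raman_synthetic_config(
    peaks = data.frame(center = c(1247, 1325), height = c(900, 1100),
                       fwhm = c(55, 60), eta = c(0.3, 0.7))))
  pk <- fit_peaks(g2$spectrum, c(1247, 1325))
  expect_lt(abs(pk[[1]]$center - 1247), 1)
  expect_lt(abs(pk[[2]]$center - 1325), 1)
  expect_error(fit_peaks(raman_spectrum(1:100 + 799, rep(0, 100)), 820),
               "fit error")
})

test_that("pipeline is scale equivariant", {
  cfg <- raman_synthetic_config(noise_sd = 0)
  g <- gen_raman_spectrum(cfg)
  pk1 <- fit_peaks(g$spectrum, c(1247, 1325))
  sp2 <- raman_spectrum(g$spectrum$wavenumber, 3.7 * g$spectrum$intensity)
  pk2 <- fit_peaks(sp2, c(1247, 1325))
  expect_equal(pk2[[1]]$height / pk1[[1]]$height, 3.7, tolerance = 1e-6)
  expect_equal(band_ratio(pk2)$ratio, band_ratio(pk1)$ratio,
               tolerance = 1e-6)
})

test_that("band assignment follows the nearest-band rule", {
  peaks <- list(list(center = 1266, height = 3484.08),
                list(center = 1304, height = 5100.98))
  br <- band_ratio(peaks)
  expect_equal(round(br$ratio, 2), 0.68)
  # one band missing -> assignment error
  expect_error(band_ratio(list(list(center = 1247, height = 1))),
               "no peak within")
  expect_error(band_ratio(list(list(center = 1100, height = 1),
                               list(center = 1150, height = 1))),
               "1247|1325")
  # a single peak inside both windows must not serve both bands
  expect_error(band_ratio(list(list(center = 1285, height = 1))),
               "same peak")
  eq <- band_ratio(list(list(center = 1247, height = 5),
                        list(center = 1325, height = 5)))
  expect_equal(eq$ratio, 1)
})

test_that("reference peak table reproduces the printed per-sample and
           group ratios", {
  tab <- example_peak_table()
  rt <- band_ratio_table(tab)
  # first 15 s and first 30 s samples, printed to 2 decimals
  r15 <- rt$ratio[rt$weld_time_s == 15][1]
  r30 <- rt$ratio[rt$weld_time_s == 30][1]
  expect_equal(r15, 3227.29 / 1409.34, tolerance = 1e-12)
  expect_equal(round(r15, 2), 2.29)
  expect_equal(round(r30, 2), 0.68)
  gm <- group_mean_ratio(rt)
  expect_equal(gm$mean_ratio[gm$weld_time_s == 15], 2.2927,
               tolerance = 0.00005)
  expect_equal(gm$mean_ratio[gm$weld_time_s == 25], 1.8351,
               tolerance = 0.00005)
  expect_equal(gm$mean_ratio[gm$weld_time_s == 30], 0.7983,
               tolerance = 0.00005)
  # 30 s group mean equals the mean of its five per-sample ratios
  expect_equal(gm$mean_ratio[gm$weld_time_s == 30],
               mean(c(0.68302, 0.72311, 0.66516, 0.98502, 0.93519)),
               tolerance = 5e-5)
  # single-ratio group is its own mean
  one <- group_mean_ratio(data.frame(weld_time_s = 99, ratio = 1.23))
  expect_equal(one$mean_ratio, 1.23)
})

test_that("full pipeline recovers the band ratio from a raw spectrum", {
  cfg <- raman_synthetic_config(
    peaks = data.frame(center = c(1247, 1325), height = c(3227, 1409),
                       fwhm = c(37, 51), eta = c(0.5, 0.5)),
    baseline = c(200, 150, -100), noise_sd = 0)
  g <- gen_raman_spectrum(cfg)
  res <- analyze_raman(g$spectrum)
  # smoothing and baseline estimation distort the heights slightly; the
  # ratio survives within a few percent
  expect_equal(res$ratio$ratio, 3227 / 1409, tolerance = 0.05)
})

test_that("batch manifests run the whole pipeline per sample", {
  dir <- withr::local_tempdir()
  mk <- function(name, h1, h2, seed) {
    g <- gen_raman_spectrum(raman_synthetic_config(
      peaks = data.frame(center = c(1247, 1325), height = c(h1, h2),
                         fwhm = c(37, 51), eta = c(0.5, 0.5)),
      baseline = c(50, 20), noise_sd = 2, seed = seed))
    write.csv(data.frame(wavenumber_cm1 = g$spectrum$wavenumber,
                         intensity = g$spectrum$intensity),
              file.path(dir, name), row.names = FALSE)
    name
  }
  manifest <- data.frame(
    file = c(mk("a.csv", 2000, 1000, 1), mk("b.csv", 1500, 1000, 2)),
    sample_id = c("a", "b"), weld_time_s = c(15, 15))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  res <- analyze_raman_batch(file.path(dir, "manifest.csv"))
  expect_equal(nrow(res$ratios), 2)
  expect_equal(res$groups$n, 2)
  expect_equal(res$groups$mean_ratio, mean(c(2, 1.5)), tolerance = 0.1)
  expect_equal(nrow(res$peaks), 4)
})
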