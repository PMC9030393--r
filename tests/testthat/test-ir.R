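# IR profile extraction, fitting degree, diffusion width, isotherm
# deviation.

test_that("profiles extract from frames with pitch-correct distances", {
  # uniform frame -> constant profile
  fr <- thermal_frame(matrix(25, 20, 30), pitch_mm = 0.2, time_s = 0)
  pr <- extract_profile(list(fr), 0, line = 10)
  expect_true(all(pr$temperature == 25))
  # linear gradient a + b x recovered within pitch quantisation
  b <- 1.7
  vals <- matrix(rep(30 + b * (0:29) * 0.2, each = 20), 20, 30)
  fr2 <- thermal_frame(vals, pitch_mm = 0.2, time_s = 0)
  pr2 <- extract_profile(list(fr2), 0, line = 5, origin_px = 1)
  slope <- coef(lm(pr2$temperature ~ pr2$distance_mm))[2]
  expect_equal(unname(slope), b, tolerance = 1e-9)
  expect_error(extract_profile(list(fr), 10, line = 1), "outside")
})

test_that("fitting degree is 100 for identical profiles and matches a
           hand-computed sum-of-squares oracle", {
  x <- seq(0, 8, by = 0.25)
  y <- 50 - 25 / 8 * x                    # spans 25..50 degC
  sim <- thermal_profile(x, y)
  expect_equal(fitting_degree(sim, sim)$fitting_degree, 100)
  # alternating +-0.5 disturbance: hand-computed R^2 on the window
  meas <- thermal_profile(x, y + 0.5 * (-1)^(seq_along(x)))
  sel <- x >= 1
  ym <- meas$temperature[sel]
  ss_res <- sum((ym - y[sel])^2)
  ss_tot <- sum((ym - mean(ym))^2)
  expect_equal(fitting_degree(sim, meas)$fitting_degree,
               100 * (1 - ss_res / ss_tot), tolerance = 1e-10)
})

test_that("fitting degree handles windows, constants and shifts", {
  x <- seq(0, 8, by = 0.25)
  sim <- thermal_profile(x, 50 - 3 * x)
  flat <- thermal_profile(x, rep(30, length(x)))
  expect_error(fitting_degree(sim, flat), "constant")
  # invariant under adding the same constant to both profiles
  meas <- thermal_profile(x, 50 - 3 * x + rnorm(length(x), 0, 0.1))
  f1 <- fitting_degree(sim, meas)$fitting_degree
  sims <- thermal_profile(x, 50 - 3 * x + 7)
  meass <- thermal_profile(x, meas$temperature + 7)
  expect_equal(fitting_degree(sims, meass)$fitting_degree, f1,
               tolerance = 1e-9)
  # nrmse alternative stays below the r2 value here but is defined
  expect_true(is.finite(fitting_degree(sim, meas,
                                       method = "nrmse")$fitting_degree))
  expect_error(fitting_degree(sim, thermal_profile(x + 100, 50 - 3 * x)),
               "overlap")
})

test_that("noisy synthetic measurement keeps fitting degree above 97%", {
  set.seed(7)
  x <- seq(0, 8, by = 0.1)
  truth <- 25 + 28 * exp(-x / 2.5)        # spans > 20 degC
  sim <- thermal_profile(x, truth)
  for (rep in 1:5) {
    meas <- thermal_profile(x, truth + rnorm(length(x), 0, 0.2))
    expect_gte(fitting_degree(sim, meas)$fitting_degree, 97)
  }
})

test_that("diffusion width interpolates the ambient crossing", {
  x <- seq(0, 5, by = 0.5)
  expect_equal(diffusion_width(thermal_profile(x, rep(25, length(x)))), 0)
  tri <- thermal_profile(x, 35 - 2 * x)   # 35 at 0 down to 25 at 5
  expect_equal(diffusion_width(tri, eps = 0.5), 4.75)
  # hot everywhere: width runs to the end of the profile
  hot <- thermal_profile(x, rep(40, length(x)))
  expect_equal(diffusion_width(hot), 5)
  expect_error(diffusion_width(tri, eps = 0), "eps")
})

test_that("deviation rate is a scale-free percentage", {
  expect_equal(round(deviation_rate(0.24, 4.32), 1), 5.6)
  expect_equal(deviation_rate(0, 10), 0)
  expect_equal(deviation_rate(1, 10), 10)
  for (c in c(0.5, 2, 13))
    expect_equal(deviation_rate(0.24 * c, 4.32 * c),
                 deviation_rate(0.24, 4.32))
  expect_error(deviation_rate(1, 0), "width")
})

test_that("isotherm z-deviation measures the constructed offset", {
  g <- build_geometry(slab_length = 10e-3, slab_width = 2e-3,
                      footprint = 2e-3, dx = 0.25e-3, dy = 0.5e-3,
                      nz_tissue = 4, nz_electrode = 1)
  arr <- array(NA_real_, dim = dim(g$label))
  xmm <- abs(g$xc) * 1e3
  ktop <- g$nz_electrode + g$nz_tissue
  kbot <- g$nz_electrode + 1L
  for (k in (kbot):(ktop)) for (j in seq_len(g$ny))
    arr[, j, k] <- 60 - 8 * xmm
  # z-uniform: zero deviation
  expect_equal(isotherm_z_deviation(arr, 40, geom = g), 0)
  # shift the bottom-surface profile outward by exactly 0.3 mm
  for (j in seq_len(g$ny))
    arr[, j, kbot] <- 60 - 8 * pmax(xmm - 0.3, 0)
  expect_equal(isotherm_z_deviation(arr, 40, geom = g), 0.3,
               tolerance = 1e-9)
  # absent isotherm errors
  arr25 <- array(25, dim = dim(g$label))
  expect_error(isotherm_z_deviation(arr25, 40, geom = g), "absent")
})

test_that("profile CSV round-trips", {
  f <- withr::local_tempfile(fileext = ".csv")
  pr <- thermal_profile(seq(0, 4, 0.5), 40 - seq(0, 4, 0.5) * 3)
  write_profile_csv(pr, f)
  pr2 <- read_profile_csv(f)
  expect_equal(pr2$distance_mm, pr$distance_mm)
  expect_equal(pr2$temperature, pr$temperature)
})

test_that("frame CSV round-trips into a thermal frame", {
  f <- withr::local_tempfile(fileext = ".csv")
  vals <- matrix(25 + runif(60), 6, 10)
  write.csv(vals, f, row.names = FALSE)
  fr <- read_frame_csv(f, pitch_mm = 0.2, time_s = 1.5)
  expect_equal(unname(fr$values), unname(vals), tolerance = 1e-12)
  expect_equal(fr$time_s, 1.5)
})
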