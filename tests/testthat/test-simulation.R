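# Coupled runs on reduced grids: drive scaling, monotonicity, energy
# balance, determinism, and output plumbing.

small_config <- function(amplitude = 6, t_end = 2, ...) {
  simulation_config(geometry = tiny_geometry(),
                    drive = drive_waveform(amplitude),
                    t_end = t_end, dt = 0.05, tol = 1e-10, ...)
}

test_that("effective drive is the RMS-equivalent voltage", {
  expect_equal(effective_drive(drive_waveform(100, duty_cycle = 1)), 100)
  expect_equal(effective_drive(drive_waveform(100, duty_cycle = 0.25)), 50)
  expect_equal(effective_drive(drive_waveform(0, duty_cycle = 0.5)), 0)
  expect_error(drive_waveform(100, duty_cycle = 0), "duty")
  expect_error(drive_waveform(-1), "amplitude")
})

test_that("zero drive never heats tissue above its initial temperature", {
  sim <- run_simulation(small_config(amplitude = 0, t_end = 1))
  expect_true(all(sim$history$tissue_max <= 25 + 1e-6))
  # electrodes start colder: tissue can only cool
  expect_lt(tail(sim$history$tissue_max, 1), 25)
})

test_that("doubling the amplitude quadruples the initial heating rate", {
  base <- run_simulation(small_config(amplitude = 0, t_end = 0.05))
  s1 <- run_simulation(small_config(amplitude = 4, t_end = 0.05))
  s2 <- run_simulation(small_config(amplitude = 8, t_end = 0.05))
  # compare central mean rise over the zero-drive baseline after 1 step
  r1 <- tail(s1$history$central_mean, 1) - tail(base$history$central_mean, 1)
  r2 <- tail(s2$history$central_mean, 1) - tail(base$history$central_mean, 1)
  expect_equal(r2 / r1, 4, tolerance = 0.01)
})

test_that("central maximum is non-decreasing under constant drive", {
  sim <- run_simulation(small_config(amplitude = 8, t_end = 3))
  expect_true(all(diff(sim$history$central_max) > -1e-9))
})

test_that("energy balance closes over a driven run", {
  cfg <- small_config(amplitude = 8, t_end = 3)
  cfg$h_air <- 0; cfg$h_sink <- 0         # insulated: Joule in = stored
  sim <- run_simulation(cfg)
  g <- cfg$geometry
  T0 <- array(NA_real_, dim = dim(g$label))
  T0[g$label == 1] <- 25
  T0[g$label > 1] <- 20
  de <- stored_energy(g, sim$T_final) - stored_energy(g, T0)
  expect_equal(de, sim$joule_energy, tolerance = 0.005 * sim$joule_energy)
  # with convection on, the balance includes the boundary loss
  cfg2 <- small_config(amplitude = 8, t_end = 3)
  cfg2$h_air <- 50; cfg2$h_sink <- 500
  sim2 <- run_simulation(cfg2)
  de2 <- stored_energy(g, sim2$T_final) - stored_energy(g, T0)
  expect_equal(de2, sim2$joule_energy - sim2$loss_energy,
               tolerance = 0.005 * abs(sim2$joule_energy))
})

test_that("runs are deterministic and record requested checkpoints", {
  cfg <- small_config(amplitude = 6, t_end = 1,
                      checkpoint_times = c(0.5, 1))
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$history, b$history)
  expect_identical(a$checkpoints, b$checkpoints)
  expect_equal(a$checkpoint_times, c(0.5, 1))
  expect_equal(dim(a$checkpoints[[1]]), dim(cfg$geometry$label))
})

test_that("simulation outputs are written as portable CSV", {
  dir <- withr::local_tempdir()
  cfg <- small_config(amplitude = 6, t_end = 0.5,
                      checkpoint_times = 0.5)
  sim <- run_simulation(cfg)
  write_simulation(sim, dir)
  expect_true(file.exists(file.path(dir, "history.csv")))
  h <- read.csv(file.path(dir, "history.csv"))
  expect_equal(h$tissue_max, sim$history$tissue_max)
  expect_gt(length(list.files(dir, pattern = "^field_")), 0)
})

test_that("grid refinement changes the short-run peak by less than 1 degC", {
  # convergence check at reduced scale: same physical slab, two
  # resolutions, constant drive
  g1 <- build_geometry(slab_length = 6e-3, slab_width = 3e-3,
                       footprint = 2e-3, dx = 0.5e-3, dy = 0.5e-3,
                       nz_tissue = 4, nz_electrode = 4)
  g2 <- build_geometry(slab_length = 6e-3, slab_width = 3e-3,
                       footprint = 2e-3, dx = 0.25e-3, dy = 0.25e-3,
                       nz_tissue = 8, nz_electrode = 8)
  mk <- function(g) simulation_config(geometry = g,
                                      drive = drive_waveform(6),
                                      t_end = 5, dt = 0.05, tol = 1e-8)
  s1 <- run_simulation(mk(g1))
  s2 <- run_simulation(mk(g2))
  expect_lt(abs(tail(s1$history$central_max, 1) -
                  tail(s2$history$central_max, 1)), 1)
})

test_that("advection is carried but must be zero", {
  expect_error(simulation_config(u = 1), "u must be 0")
  expect_equal(simulation_config()$u, 0)
})
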