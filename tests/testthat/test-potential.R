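# Quasi-static potential solver: closed-form cases and the dense-matrix
# oracle (independent assembly + base-R solve).

test_that("uniform-conductivity parallel plate gives a linear potential", {
  g <- plate_geometry(nz_tissue = 4)
  sigma <- array(0.25, dim = dim(g$label))
  out <- solve_potential(g, sigma, 10, tol = 1e-12)
  # tissue layers sit between the Dirichlet plates: V linear in z
  expected <- c(0, 2, 4, 6, 8, 10)
  for (i in seq_len(g$nx)) for (j in seq_len(g$ny))
    expect_equal(out$V[i, j, ], expected, tolerance = 1e-9)
})

test_that("two-layer stack splits the voltage like series resistors", {
  g <- plate_geometry(nz_tissue = 4)
  sigma <- array(5.7e7, dim = dim(g$label))   # electrodes
  sigma[, , 2:3] <- 0.4   # lower two tissue layers twice as conductive
  sigma[, , 4:5] <- 0.2
  out <- solve_potential(g, sigma, 9, tol = 1e-12)
  # series-resistor closed form (cell-centred): with J = 9 / (15 dz / 0.6),
  # the two layer centres adjacent to the material interface sit at
  # V = 2.25 and 4.5; the interface itself at 3 (drop split 1 : 2)
  expect_equal(out$V[1, 1, 3], 2.25, tolerance = 1e-6)
  expect_equal(out$V[1, 1, 4], 4.5, tolerance = 1e-6)
  drop_lo <- out$V[1, 1, 3] + (out$V[1, 1, 4] - out$V[1, 1, 3]) / 3
  expect_equal(drop_lo, 3, tolerance = 1e-6)      # interface potential
  expect_equal((9 - drop_lo) / drop_lo, 2, tolerance = 1e-6)
})

test_that("zero applied voltage gives an identically zero field", {
  g <- tiny_geometry()
  sigma <- array(0.25, dim = dim(g$label))
  out <- solve_potential(g, sigma, 0)
  expect_true(all(abs(out$V[g$label > 0]) < 1e-12))
})

test_that("solver matches a dense-matrix oracle on small grids", {
  cases <- list(
    list(geom = tiny_geometry(nz_tissue = 3, nz_electrode = 1),
         sigma_fun = function(n) rep(0.25, n)),
    list(geom = plate_geometry(nz_tissue = 5),
         sigma_fun = function(n) seq(0.1, 0.6, length.out = n)),
    list(geom = build_geometry(slab_length = 5e-3, slab_width = 2e-3,
                               footprint = 2e-3, dx = 0.5e-3, dy = 0.5e-3,
                               nz_tissue = 1, nz_electrode = 1),
         sigma_fun = function(n) 0.2 + 0.2 * sin(seq_len(n))^2))
  for (cs in cases) {
    g <- cs$geom
    sigma <- array(cs$sigma_fun(length(g$label)), dim = dim(g$label))
    out <- solve_potential(g, sigma, 5, tol = 1e-13)
    sys <- dense_potential_system(g, sigma, 5)
    v_dense <- solve(sys$A, sys$b)
    v_pkg <- out$V[sys$unknowns]
    # the package solution satisfies the independently assembled system
    resid <- sqrt(sum((sys$A %*% v_pkg - sys$b)^2)) / sqrt(sum(sys$b^2))
    expect_lt(resid, 1e-8)
    expect_equal(v_pkg, as.numeric(v_dense), tolerance = 1e-8)
  }
})

test_that("non-positive conductivity on conducting cells is rejected", {
  g <- tiny_geometry()
  sigma <- array(0.25, dim = dim(g$label))
  sigma[g$label == 1][1] <- 0
  expect_error(solve_potential(g, sigma, 5), "sigma")
})

test_that("joule power matches sigma |grad V|^2 and the power balance", {
  g <- plate_geometry(nz_tissue = 4)
  sigma <- array(5.7e7, dim = dim(g$label))
  sigma[g$label == 1] <- 0.24567
  # choose V so that |grad V| = 1000 V/m across 4 tissue layers
  v_app <- 1000 * 4 * g$dz
  out <- solve_potential(g, sigma, v_app, tol = 1e-12)
  jp <- joule_power(g, out$V, sigma, v_app)
  q_tissue <- jp$q[g$label == 1]
  expect_equal(mean(q_tissue), 0.24567 * 1000^2, tolerance = 1e-6)
  # discrete power balance: total dissipation = V * I
  expect_equal(jp$total_power, v_app * jp$source_current,
               tolerance = 1e-10)
  # zero potential -> zero source
  z <- joule_power(g, array(0, dim = dim(g$label)), sigma, 0)
  expect_true(all(z$q == 0))
})

test_that("power balance holds on a heterogeneous two-layer stack", {
  g <- plate_geometry(nz_tissue = 4)
  sigma <- array(5.7e7, dim = dim(g$label))
  sigma[, , 2:3] <- 0.4
  sigma[, , 4:5] <- 0.2
  out <- solve_potential(g, sigma, 9, tol = 1e-12)
  jp <- joule_power(g, out$V, sigma, 9)
  vol <- g$dx * g$dy * g$dz
  expect_equal(sum(jp$q) * vol, 9 * jp$source_current,
               tolerance = 1e-3 * 9 * jp$source_current)
  expect_true(all(jp$q >= 0))
})
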