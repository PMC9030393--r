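# Shared fixtures: small geometries and material sets used across the
# solver tests.  Everything is generated in code; no binary fixtures.

# a small but fully featured weld geometry (electrodes + exposed edge)
tiny_geometry <- function(nz_tissue = 4, nz_electrode = 2) {
  build_geometry(slab_length = 6e-3, slab_width = 3e-3,
                 thickness = 0.958e-3, footprint = 2e-3,
                 dx = 0.5e-3, dy = 0.5e-3,
                 nz_tissue = nz_tissue, nz_electrode = nz_electrode)
}

# parallel-plate stack: electrodes cover the whole slab (edge area empty)
plate_geometry <- function(nz_tissue = 4, dx = 0.5e-3) {
  build_geometry(slab_length = 2e-3, slab_width = 2e-3,
                 thickness = 1e-3, footprint = 2e-3,
                 dx = dx, dy = dx, nz_tissue = nz_tissue, nz_electrode = 1)
}

# material set in which the electrodes are made of tissue: a uniform
# medium, used for exact conservation / heating-rate checks
uniform_materials <- function() {
  tp <- tissue_properties()
  list(tissue = tp, upper_electrode = tp, lower_electrode = tp)
}

# dense assembly of the discrete potential system (independent oracle):
# unknowns are tissue cells, Dirichlet electrodes, harmonic-mean faces
dense_potential_system <- function(geom, sigma, v_applied) {
  lab <- geom$label
  n <- length(lab)
  unk <- which(lab == 1L & sigma > 0)
  uid <- rep(NA_integer_, n)
  uid[unk] <- seq_along(unk)
  dims <- dim(lab)
  area <- c(geom$dy * geom$dz, geom$dx * geom$dz, geom$dx * geom$dy)
  dist <- c(geom$dx, geom$dy, geom$dz)
  stride <- c(1L, dims[1], dims[1] * dims[2])
  A <- matrix(0, length(unk), length(unk))
  b <- numeric(length(unk))
  pos <- arrayInd(seq_len(n), dims)
  for (p in seq_along(unk)) {
    c1 <- unk[p]
    for (ax in 1:3) for (dir in c(-1L, 1L)) {
      pp <- pos[c1, ax] + dir
      if (pp < 1L || pp > dims[ax]) next
      c2 <- c1 + dir * stride[ax]
      if (lab[c2] == 0L || sigma[c2] <= 0) next
      g <- area[ax] / dist[ax] *
        2 * sigma[c1] * sigma[c2] / (sigma[c1] + sigma[c2])
      A[p, p] <- A[p, p] + g
      if (!is.na(uid[c2])) {
        A[p, uid[c2]] <- A[p, uid[c2]] - g
      } else {
        vfix <- if (lab[c2] == 2L) v_applied else 0
        b[p] <- b[p] + g * vfix
      }
    }
  }
  list(A = A, b = b, unknowns = unk)
}

# total thermal energy (J) relative to 0 degC of a field state
stored_energy <- function(geom, T, materials = default_materials()) {
  vol <- geom$dx * geom$dy * geom$dz
  codes <- c(tissue = 1L, upper_electrode = 2L, lower_electrode = 3L)
  e <- 0
  for (nm in names(codes)) {
    sel <- geom$label == codes[[nm]]
    p <- materials[[nm]]
    e <- e + sum(T[sel]) * p$density * p$heat_capacity * vol
  }
  e
}
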