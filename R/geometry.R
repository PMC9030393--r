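# Weld geometry: a tissue slab clamped between two copper electrodes.
# x spans the heat-spread direction (origin at the slab centre), y the
# electrode length, z the slab thickness.  Cells are cell-centred and
# labelled air / tissue / upper_electrode / lower_electrode; the electrode
# footprint is centred on x and spans the full y extent.

.REGION_LEVELS <- c("air", "tissue", "upper_electrode", "lower_electrode")
.REGION_CODE <- c(air = 0L, tissue = 1L, upper_electrode = 2L,
                  lower_electrode = 3L)

#' Build the weld geometry
#'
#' Constructs the labelled voxel grid: a tissue slab of
#' `slab_length` x `slab_width` x `thickness`, with electrode blocks of
#' footprint `footprint` (along x, full width along y) pressed on both
#' faces.  The probe regions are `central_area` (tissue under the
#' electrodes, invisible to an IR camera) and `edge_area` (exposed tissue).
#'
#' @param slab_length Tissue extent along x (m). Default 20 mm.
#' @param slab_width Tissue extent along y (m). Default 10 mm.
#' @param thickness Tissue thickness (m). Default 0.958 mm, the compressed
#'   vessel-wall thickness.
#' @param footprint Electrode footprint along x (m). Default 3 mm. Must not
#'   exceed `slab_length`.
#' @param dx,dy Cell size along x and y (m). Default 0.2 mm.
#' @param nz_tissue Number of tissue cells across the thickness (>= 1);
#'   sets `dz = thickness / nz_tissue`.
#' @param nz_electrode Number of electrode cells on each side (>= 1).
#'   The default (8, ~0.96 mm of copper) models the thermally
#'   participating contact plate of the forceps jaw.
#' @return An object of class `weld_geometry`: grid dimensions and
#'   spacings, integer label array, cell-centre coordinates (m), index sets
#'   `central_idx` / `edge_idx` (1-based cell indices into the flattened
#'   grid), and the electrode edge position `edge_x` (m).
#' @export
build_geometry <- function(slab_length = 20e-3, slab_width = 10e-3,
                           thickness = 0.958e-3, footprint = 3e-3,
                           dx = 0.2e-3, dy = 0.2e-3,
                           nz_tissue = 8, nz_electrode = 8) {
  stopifnot(slab_length > 0, slab_width > 0, thickness > 0, footprint > 0,
            dx > 0, dy > 0, nz_tissue >= 1, nz_electrode >= 1)
  if (footprint > slab_length + 1e-12)
    stop("electrode footprint exceeds the tissue slab")
  nx <- max(1L, as.integer(round(slab_length / dx)))
  ny <- max(1L, as.integer(round(slab_width / dy)))
  dz <- thickness / nz_tissue
  nz <- nz_tissue + 2L * nz_electrode
  nf <- max(1L, as.integer(round(footprint / dx)))
  if (nf > nx) nf <- nx
  f0 <- (nx - nf) %/% 2L + 1L         # first footprint cell (1-based)
  f1 <- f0 + nf - 1L

  lab <- array(.REGION_CODE[["air"]], dim = c(nx, ny, nz))
  kt <- nz_electrode + seq_len(nz_tissue)          # tissue layers
  lab[, , kt] <- .REGION_CODE[["tissue"]]
  lab[f0:f1, , seq_len(nz_electrode)] <- .REGION_CODE[["lower_electrode"]]
  lab[f0:f1, , nz - nz_electrode + seq_len(nz_electrode)] <-
    .REGION_CODE[["upper_electrode"]]

  xc <- (seq_len(nx) - 0.5) * dx - nx * dx / 2
  yc <- (seq_len(ny) - 0.5) * dy - ny * dy / 2
  zc <- (seq_len(nz) - 0.5) * dz - nz_electrode * dz  # z = 0 at tissue base

  foot <- logical(nx); foot[f0:f1] <- TRUE
  tissue_mask <- lab == .REGION_CODE[["tissue"]]
  central_mask <- tissue_mask & array(foot, dim = c(nx, ny, nz))
  central_idx <- which(central_mask)
  edge_idx <- which(tissue_mask & !central_mask)

  structure(
    list(nx = nx, ny = ny, nz = nz, dx = dx, dy = dy, dz = dz,
         nz_tissue = nz_tissue, nz_electrode = nz_electrode,
         label = lab, xc = xc, yc = yc, zc = zc,
         footprint_cells = c(f0, f1),
         edge_x = (f1 - nx / 2) * dx,   # +x face of the electrode block
         thickness = thickness, slab_length = slab_length,
         slab_width = slab_width, footprint = footprint,
         central_idx = central_idx, edge_idx = edge_idx),
    class = "weld_geometry")
}

#' @export
print.weld_geometry <- function(x, ...) {
  cat(sprintf("<weld_geometry %d x %d x %d cells (%.3g x %.3g x %.3g mm)>\n",
              x$nx, x$ny, x$nz, x$nx * x$dx * 1e3, x$ny * x$dy * 1e3,
              x$nz * x$dz * 1e3))
  cat(sprintf("  tissue thickness %.4g mm (%d cells), electrodes %d cells/side\n",
              x$thickness * 1e3, x$nz_tissue, x$nz_electrode))
  cat(sprintf("  footprint cells %d..%d, central %d cells, edge %d cells\n",
              x$footprint_cells[1], x$footprint_cells[2],
              length(x$central_idx), length(x$edge_idx)))
  invisible(x)
}

#' Region label of each cell
#'
#' @param geom A [build_geometry()] object.
#' @return Character array of region labels with the grid's dimensions.
#' @export
region_labels <- function(geom) {
  stopifnot(inherits(geom, "weld_geometry"))
  array(.REGION_LEVELS[geom$label + 1L], dim = dim(geom$label))
}

# top tissue layer index (k) of a geometry
.k_tissue_top <- function(geom) geom$nz_electrode + geom$nz_tissue
.k_tissue_bottom <- function(geom) geom$nz_electrode + 1L
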