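# ---------------------------------------------------------------------------
# Synthetic 3D image phantoms emulating light-sheet volumes of layered skin:
# a bright dense epidermis band over a dimmer dermis on a bone core, with
# Gaussian-blob nuclei and optional additive noise.
#
# Coordinates are voxel-centered, 0-based, with x the fastest axis and z the
# slowest (R array dim = c(nx, ny, nz)).
# ---------------------------------------------------------------------------

#' Generate a layered dome image phantom
#'
#' A spherical dome: epidermis band (brightest) of thickness `h_epid` at the
#' outer surface, dermis band below it, bone core inside. `n_cells` Gaussian
#' blobs are placed in the skin shell with pairwise separation greater than
#' twice the cell radius, and their true centroids recorded. Seeded additive
#' Gaussian noise is applied last and intensities are clipped to `[0, 1]`.
#'
#' @param shape integer triple `(nx, ny, nz)` of voxel counts
#' @param h_epid,h_dermis layer thicknesses in voxels
#' @param n_cells number of nuclear blobs to place
#' @param noise_sd additive Gaussian noise standard deviation (intensity)
#' @param seed integer seed for cell placement and noise
#' @param cell_radius blob radius in voxels (Gaussian sigma = radius / 2)
#' @param levels named intensities for `epidermis`, `dermis`, `bone` bands
#' @param voxel_size physical length per voxel (isotropic)
#' @return an `image_phantom`: `stack` (nuclear-stain channel: layer bands
#'   plus cells, in `[0,1]`), `cell_stack` (proliferation-label channel:
#'   cells only, as imaged separately from the nuclear stain), `voxel_size`,
#'   analytic `truth_outer_surface` / `truth_inner_surface` (spheres),
#'   `truth_cells` (0-based voxel coordinates), `truth_bone_mask`
#' @export
make_image_phantom <- function(shape = c(64, 64, 48), h_epid = 4, h_dermis = 12,
                               n_cells = 0, noise_sd = 0, seed = 1L,
                               cell_radius = 3,
                               levels = c(epidermis = 0.55, dermis = 0.25,
                                          bone = 0.08),
                               voxel_size = 1) {
  stopifnot(length(shape) == 3, n_cells >= 0, noise_sd >= 0, h_epid > 0,
            h_dermis > 0)
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  R_out <- 0.9 * min(cx, cy)
  cz <- 0.85 * (nz - 1) - R_out
  if (R_out <= h_epid + h_dermis + cell_radius + 2)
    stop("stack too small for the requested layer thicknesses")
  R_ed <- R_out - h_epid
  R_db <- R_ed - h_dermis

  xs <- (0:(nx - 1)) - cx
  ys <- (0:(ny - 1)) - cy
  zs <- (0:(nz - 1)) - cz
  r <- sqrt(outer(outer(xs^2, ys^2, "+"), zs^2, "+"))

  # soft one-voxel crossfade at each boundary for subvoxel edge localization
  clamp01 <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }
  w <- 0.5
  band <- function(r, a, b) clamp01((b - r) / w + 0.5) * clamp01((r - a) / w + 0.5)
  stack <- levels[["epidermis"]] * band(r, R_ed, R_out) +
           levels[["dermis"]] * band(r, R_db, R_ed) +
           levels[["bone"]] * band(r, -Inf, R_db)

  truth_cells <- matrix(numeric(0), 0, 3)
  cell_stack <- array(0, dim(stack))
  if (n_cells > 0) {
    truth_cells <- local_seed(seed, {
      placed <- matrix(0, 0, 3)
      tries <- 0L
      lim <- 500L * n_cells
      while (nrow(placed) < n_cells && tries < lim) {
        tries <- tries + 1L
        p <- c(runif(1, 0, nx - 1), runif(1, 0, ny - 1), runif(1, 0, nz - 1))
        rr <- sqrt(sum((p - c(cx, cy, cz))^2))
        if (rr < R_db + cell_radius || rr > R_out - cell_radius) next
        if (p[3] < cz) next    # keep cells in the upper dome
        if (nrow(placed) > 0 &&
            min(sqrt(rowSums(sweep(placed, 2, p)^2))) <= 2 * cell_radius) next
        placed <- rbind(placed, p)
      }
      if (nrow(placed) < n_cells)
        stop("could not place ", n_cells, " cells with separation > ",
             2 * cell_radius, " voxels; placed only ", nrow(placed))
      placed
    })
    sig <- cell_radius / 2
    amp <- 0.4
    rad <- ceiling(3 * sig)
    for (cidx in seq_len(nrow(truth_cells))) {
      p <- truth_cells[cidx, ]
      i0 <- max(0, floor(p[1] - rad)):min(nx - 1, ceiling(p[1] + rad))
      j0 <- max(0, floor(p[2] - rad)):min(ny - 1, ceiling(p[2] + rad))
      k0 <- max(0, floor(p[3] - rad)):min(nz - 1, ceiling(p[3] + rad))
      d2 <- outer(outer((i0 - p[1])^2, (j0 - p[2])^2, "+"), (k0 - p[3])^2, "+")
      cell_stack[i0 + 1, j0 + 1, k0 + 1] <- cell_stack[i0 + 1, j0 + 1, k0 + 1] +
        amp * exp(-d2 / (2 * sig^2))
    }
    stack <- stack + cell_stack
  }
  if (noise_sd > 0) {
    noise <- local_seed(seed + 104729L, {
      array(rnorm(2 * length(stack), 0, noise_sd), dim = c(dim(stack), 2))
    })
    stack <- stack + noise[, , , 1]
    cell_stack <- cell_stack + noise[, , , 2]
  }
  stack[stack < 0] <- 0
  stack[stack > 1] <- 1
  cell_stack[cell_stack < 0] <- 0
  cell_stack[cell_stack > 1] <- 1

  structure(list(
    stack = stack, cell_stack = cell_stack, voxel_size = voxel_size,
    truth_outer_surface = list(type = "sphere", center = c(cx, cy, cz),
                               radius = R_out),
    truth_inner_surface = list(type = "sphere", center = c(cx, cy, cz),
                               radius = R_ed),
    truth_cells = truth_cells,
    truth_bone_mask = r < R_db,
    meta = list(shape = shape, h_epid = h_epid, h_dermis = h_dermis,
                n_cells = n_cells, noise_sd = noise_sd, seed = seed,
                cell_radius = cell_radius, levels = levels)),
    class = "image_phantom")
}

#' @export
print.image_phantom <- function(x, ...) {
  d <- dim(x$stack)
  cat("<image_phantom>", paste(d, collapse = " x "), "voxels,",
      nrow(x$truth_cells), "cells, noise sd", x$meta$noise_sd, "\n")
  invisible(x)
}

#' Layer masks of a phantom from its analytic ground truth
#'
#' @param phantom an `image_phantom`
#' @return named list of logical arrays (`epidermis`, `dermis`, `bone`)
#' @export
phantom_layer_masks <- function(phantom) {
  d <- dim(phantom$stack)
  ctr <- phantom$truth_outer_surface$center
  xs <- (0:(d[1] - 1)) - ctr[1]
  ys <- (0:(d[2] - 1)) - ctr[2]
  zs <- (0:(d[3] - 1)) - ctr[3]
  r <- sqrt(outer(outer(xs^2, ys^2, "+"), zs^2, "+"))
  R_out <- phantom$truth_outer_surface$radius
  R_ed <- phantom$truth_inner_surface$radius
  R_db <- R_ed - phantom$meta$h_dermis
  list(epidermis = r >= R_ed & r <= R_out,
       dermis = r >= R_db & r < R_ed,
       bone = r < R_db)
}
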