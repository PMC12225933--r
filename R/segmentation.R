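# ---------------------------------------------------------------------------
# Volumetric segmentation stage: 3D Canny edges on the nuclear-stain volume,
# oriented point clouds from intensity gradients, implicit surface
# reconstruction, epidermis thickness mapping, and principal-curvature
# detection of labeled nuclei.
#
# Voxel coordinates are 0-based and voxel-centered; x is the fastest axis,
# z the slowest (array dim = c(nx, ny, nz)).
# ---------------------------------------------------------------------------

#' 3D Canny edge detection
#'
#' Gaussian smoothing, central-difference gradients, non-maximum suppression
#' along the gradient direction (trilinear interpolation), then
#' double-threshold hysteresis with 26-connectivity. The nonzero voxels form
#' point clouds on the intensity step surfaces.
#'
#' @param stack 3D numeric array
#' @param sigma smoothing scale in voxels
#' @param low,high hysteresis thresholds on gradient magnitude; `NULL`
#'   selects them as fractions of the strongest ridge response (the maximum
#'   gradient magnitude over non-maximum-suppression survivors), which keeps
#'   interfaces of different contrast without tracking noise ridges
#' @param low_frac,high_frac fractions used when `low`/`high` are `NULL`
#' @return integer 3D array, 1 at retained edge voxels
#' @export
canny_edges_3d <- function(stack, sigma = 1.5, low = NULL, high = NULL,
                           low_frac = 0.2, high_frac = 0.4) {
  stopifnot(length(dim(stack)) == 3, sigma > 0)
  g <- cpp_smooth_gradient(stack, dim(stack), sigma)
  if (!any(g$magnitude > 0)) return(array(0L, dim(stack)))
  if (is.null(low) || is.null(high)) {
    cand <- cpp_canny_nms_hysteresis(g$magnitude, g$gx, g$gy, g$gz,
                                     dim(stack), 1e-12, 1e-12)
    mref <- max(g$magnitude[cand == 1])
    if (is.null(low)) low <- low_frac * mref
    if (is.null(high)) high <- high_frac * mref
  }
  if (!(low >= 0 && low < high)) stop("thresholds must satisfy 0 <= low < high")
  cpp_canny_nms_hysteresis(g$magnitude, g$gx, g$gy, g$gz, dim(stack), low, high)
}

#' Voxel coordinates of nonzero voxels
#' @param mask 3D array
#' @return matrix of 0-based `(x, y, z)` voxel coordinates
#' @export
mask_to_points <- function(mask) {
  idx <- which(mask != 0)
  d <- dim(mask)
  i <- (idx - 1) %% d[1]
  j <- ((idx - 1) %/% d[1]) %% d[2]
  k <- (idx - 1) %/% (d[1] * d[2])
  cbind(x = i, y = j, z = k)
}

#' Label connected components of a binary volume (26-connectivity)
#' @param mask 3D array, nonzero = foreground
#' @return integer array of component labels (0 = background)
#' @export
label_components_3d <- function(mask) {
  cpp_label3d(as.integer(mask != 0), dim(mask))
}

#' Estimate outward surface normals from the intensity gradient
#'
#' The normal at each edge point is the negated, normalized smoothed
#' intensity gradient, so it points from high to low intensity — outward
#' from tissue. Points with vanishing gradient are dropped (count reported
#' via a message and the `dropped` attribute).
#'
#' @param stack 3D numeric array
#' @param points matrix of 0-based voxel coordinates
#' @param sigma gradient smoothing scale in voxels
#' @return an `oriented_point_cloud`: `points`, unit `normals`
#' @export
estimate_normals <- function(stack, points, sigma = 1.5) {
  if (!nrow(points)) stop("points must be nonempty")
  g <- cpp_smooth_gradient(stack, dim(stack), sigma)
  idx <- cbind(points[, 1] + 1, points[, 2] + 1, points[, 3] + 1)
  gv <- cbind(g$gx[idx], g$gy[idx], g$gz[idx])
  nn <- sqrt(rowSums(gv^2))
  ok <- nn > 1e-12
  if (any(!ok))
    message("estimate_normals: dropped ", sum(!ok), " zero-gradient point(s)")
  normals <- -gv[ok, , drop = FALSE] / nn[ok]
  structure(list(points = points[ok, , drop = FALSE], normals = normals,
                 dropped = sum(!ok)),
            class = "oriented_point_cloud")
}

#' @export
print.oriented_point_cloud <- function(x, ...) {
  cat("<oriented_point_cloud>", nrow(x$points), "points\n")
  invisible(x)
}

# mean alignment of normals within spatial bins; low values signal
# incoherent orientation
normal_coherence <- function(cloud, bin = 4) {
  b <- floor(cloud$points / bin)
  key <- paste(b[, 1], b[, 2], b[, 3])
  co <- tapply(seq_len(nrow(cloud$points)), key, function(ii) {
    if (length(ii) < 2) return(NA_real_)
    m <- colMeans(cloud$normals[ii, , drop = FALSE])
    ml <- sqrt(sum(m^2))
    if (ml < 1e-12) return(0)
    mean(cloud$normals[ii, , drop = FALSE] %*% (m / ml))
  })
  mean(unlist(co), na.rm = TRUE)
}

#' Reconstruct a triangle surface from an oriented point cloud
#'
#' Builds an implicit moving-least-squares signed-distance field from the
#' oriented points on a regular grid, extracts the zero level set by marching
#' tetrahedra, and applies Taubin smoothing. The result represents the cloud
#' in a much lighter format: its vertex count is far below the point count,
#' and vertices lie within a stated Hausdorff tolerance of the cloud.
#'
#' @param cloud an `oriented_point_cloud` with at least 100 coherently
#'   oriented points
#' @param spacing grid spacing (resolution control); larger = lighter surface
#' @param smooth_iterations Taubin smoothing passes
#' @param component `"largest"` keeps the largest connected surface patch
#' @return a `tri_surface` with outward-oriented faces
#' @export
reconstruct_surface <- function(cloud, spacing = 2, smooth_iterations = 10,
                                component = c("largest", "all")) {
  component <- match.arg(component)
  if (nrow(cloud$points) < 100)
    stop("need at least 100 oriented points for reconstruction")
  if (normal_coherence(cloud, bin = 2 * spacing) < 0.5)
    stop("incoherent point normals (mean neighbor alignment < 0.5); ",
         "re-orient the cloud before reconstruction")
  lo <- apply(cloud$points, 2, min) - 3 * spacing
  hi <- apply(cloud$points, 2, max) + 3 * spacing
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  f <- cpp_imls_grid(cloud$points, cloud$normals, lo, spacing, dims,
                     2.0 * spacing)$f
  mt <- cpp_marching_tets(f, dims, lo, spacing)
  if (nrow(mt$vertices) == 0) stop("reconstruction produced an empty surface")
  verts <- cpp_taubin_smooth(mt$vertices, mt$faces, smooth_iterations,
                             0.5, -0.53)
  faces <- mt$faces + 1L
  surf <- new_tri_surface(verts, faces, meta = list(spacing = spacing,
                                                    n_input_points = nrow(cloud$points)))
  surf <- drop_degenerate_faces(surf)
  if (component == "largest") surf <- largest_component(surf)
  surf
}

drop_degenerate_faces <- function(surface, tol = 1e-12) {
  v <- surface$vertices; f <- surface$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  area <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  keep_faces <- area > tol & f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  compact_surface(new_tri_surface(v, f[keep_faces, , drop = FALSE],
                                  surface$scalars, surface$meta))
}

# drop unreferenced vertices, remapping faces (per-vertex scalars follow)
compact_surface <- function(surface) {
  used <- sort(unique(as.integer(surface$faces)))
  remap <- integer(nrow(surface$vertices))
  remap[used] <- seq_along(used)
  sc <- lapply(surface$scalars, function(s) s[used])
  new_tri_surface(surface$vertices[used, , drop = FALSE],
                  matrix(remap[surface$faces], ncol = 3), sc, surface$meta)
}

largest_component <- function(surface) {
  e <- surface_edges(surface)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(surface$vertices) - igraph::vcount(g)))
  comp <- igraph::components(g)
  if (comp$no <= 1) return(surface)
  big <- which.max(comp$csize)
  keep_v <- comp$membership == big
  keep_f <- keep_v[surface$faces[, 1]]
  compact_surface(new_tri_surface(surface$vertices,
                                  surface$faces[keep_f, , drop = FALSE],
                                  surface$scalars, surface$meta))
}

#' Epidermis thickness map
#'
#' Distance from each vertex of the outer surface to the inner surface along
#' the inward normal (ray casting); rays that miss fall back to the nearest
#' point on the inner surface. A warning reports the miss fraction when it
#' exceeds 10%.
#'
#' @param outer,inner `tri_surface` objects; `inner` lies on the interior
#'   side of `outer`
#' @return numeric per-vertex thickness on `outer`, with attribute
#'   `miss_fraction`
#' @export
thickness_map <- function(outer, inner) {
  nrm <- surface_normals(outer)
  th <- cpp_ray_thickness(outer$vertices, -nrm, inner$vertices,
                          inner$faces - 1L)
  miss <- th < 0
  if (any(miss)) {
    th[miss] <- cpp_dist_to_surface(outer$vertices[miss, , drop = FALSE],
                                    inner$vertices, inner$faces - 1L)
  }
  frac <- mean(miss)
  if (frac > 0.10)
    warning(sprintf("thickness_map: %.1f%% of rays missed the inner surface",
                    100 * frac))
  attr(th, "miss_fraction") <- frac
  th
}

#' Detect bright blob-like cells by 3D principal curvatures
#'
#' The stack is smoothed at the cell scale; at each voxel the Hessian's three
#' eigenvalues are computed. Voxels where all three principal curvatures are
#' negative (a bright blob) and the smallest-magnitude one exceeds the
#' threshold are merged into score-weighted component centroids.
#'
#' @param stack 3D numeric array (cells bright on dark)
#' @param scale smoothing scale in voxels, matched to the cell radius
#' @param curvature_threshold magnitude threshold on the smallest principal
#'   curvature
#' @return a `cell_detection`: `centroids` (0-based voxel coords), `scores`
#' @export
detect_cells <- function(stack, scale = 1.5, curvature_threshold = 0.01) {
  stopifnot(length(dim(stack)) == 3, scale > 0, curvature_threshold > 0)
  r <- cpp_blob_detect(stack, dim(stack), scale, curvature_threshold)
  structure(list(centroids = r$centroids, scores = r$scores,
                 scale = scale, threshold = curvature_threshold),
            class = "cell_detection")
}

#' @export
print.cell_detection <- function(x, ...) {
  cat("<cell_detection>", nrow(x$centroids), "cells\n")
  invisible(x)
}

#' Per-layer proliferating-cell densities
#'
#' Counts detected centroids inside each layer mask and divides by the mask
#' volume. A homogeneity statistic is reported per layer: the coefficient of
#' variation of counts over `n_bins` near-equal-volume slabs of the mask
#' (split along x at volume quantiles); for spatially homogeneous (Poisson)
#' proliferation the expected CV is `1/sqrt(mean count per bin)`.
#'
#' @param cells a `cell_detection`
#' @param layer_masks named list of disjoint logical 3D arrays
#' @param voxel_size physical length per voxel
#' @param n_bins number of equal-volume spatial bins per layer
#' @return data frame with `layer`, `n_cells`, `volume`, `density`,
#'   `cv_binned`, `cv_poisson`; empty masks yield `NA` density
#' @export
proliferation_density <- function(cells, layer_masks, voxel_size = 1,
                                  n_bins = 8) {
  # disjointness
  tot <- Reduce(`+`, lapply(layer_masks, function(m) as.integer(m != 0)))
  if (any(tot > 1)) stop("layer masks must be disjoint")
  cen <- cells$centroids
  out <- lapply(names(layer_masks), function(nm) {
    m <- layer_masks[[nm]]
    vol_vox <- sum(m)
    if (vol_vox == 0) {
      return(data.frame(layer = nm, n_cells = NA_integer_, volume = NA_real_,
                        density = NA_real_, cv_binned = NA_real_,
                        cv_poisson = NA_real_))
    }
    inside <- rep(FALSE, nrow(cen))
    if (nrow(cen)) {
      ii <- pmin(pmax(round(cen) + 1, 1), matrix(rep(dim(m), each = nrow(cen)),
                                                 ncol = 3))
      inside <- m[ii] != 0
    }
    n <- sum(inside)
    vol <- vol_vox * voxel_size^3
    # equal-volume x-slabs of the mask
    vox_x <- mask_to_points(m)[, 1]
    breaks <- unique(quantile(vox_x, probs = seq(0, 1, length.out = n_bins + 1)))
    cv <- NA_real_
    cvp <- NA_real_
    if (length(breaks) > 2 && n > 0) {
      cx <- cen[inside, 1]
      bin <- cut(cx, breaks = breaks, include.lowest = TRUE)
      counts <- as.vector(table(bin))
      if (mean(counts) > 0) {
        cv <- sd(counts) / mean(counts)
        cvp <- 1 / sqrt(mean(counts))
      }
    }
    data.frame(layer = nm, n_cells = n, volume = vol, density = n / vol,
               cv_binned = cv, cv_poisson = cvp)
  })
  do.call(rbind, out)
}

#' Segment the two skin surfaces of a nuclear-stain volume
#'
#' Convenience pipeline: Canny edges, split into connected components, keep
#' the two largest (outer epidermis surface and epidermis-dermis boundary),
#' estimate normals, and reconstruct both surfaces. Components are ordered by
#' mean distance to the stack center so the outer surface comes first.
#'
#' @param stack 3D numeric array
#' @param sigma Canny smoothing scale
#' @param spacing reconstruction grid spacing
#' @return list with `outer`, `inner` (`tri_surface`), `edges` (binary array)
#' @export
segment_skin_surfaces <- function(stack, sigma = 1.5, spacing = 2) {
  edges <- canny_edges_3d(stack, sigma = sigma)
  lab <- label_components_3d(edges)
  sizes <- tabulate(lab[lab > 0])
  if (length(sizes) < 2)
    stop("expected at least two edge components (two nested surfaces), got ",
         length(sizes))
  top2 <- order(sizes, decreasing = TRUE)[1:2]
  pts <- lapply(top2, function(l) mask_to_points(lab == l))
  # order by mean radius about the volume centroid of all edge voxels
  allp <- mask_to_points(edges)
  ctr <- colMeans(allp)
  mr <- vapply(pts, function(p) mean(sqrt(rowSums(sweep(p, 2, ctr)^2))), 0)
  outer_pts <- pts[[which.max(mr)]]
  inner_pts <- pts[[which.min(mr)]]
  clo <- estimate_normals(stack, outer_pts, sigma)
  cli <- estimate_normals(stack, inner_pts, sigma)
  list(outer = reconstruct_surface(clo, spacing = spacing),
       inner = reconstruct_surface(cli, spacing = spacing),
       edges = edges)
}
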