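# ---------------------------------------------------------------------------
# Triangle surfaces: the light-weight representation shared by the
# segmentation stage (reconstructed from point clouds) and the simulator
# (deformed free surfaces).
# ---------------------------------------------------------------------------

new_tri_surface <- function(vertices, faces, scalars = list(), meta = list()) {
  structure(list(vertices = vertices, faces = faces,
                 scalars = scalars, meta = meta),
            class = "tri_surface")
}

#' @export
print.tri_surface <- function(x, ...) {
  cat("<tri_surface>", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  if (length(x$scalars))
    cat("  scalars:", paste(names(x$scalars), collapse = ", "), "\n")
  invisible(x)
}

#' Total area of a triangle surface
#' @param surface a `tri_surface`
#' @return total area
#' @export
surface_area <- function(surface) {
  cpp_surface_area(surface$vertices, surface$faces - 1L)
}

#' Angle-area-weighted outward vertex normals
#' @param surface a `tri_surface` with outward-oriented faces
#' @return matrix of unit normals, one row per vertex
#' @export
surface_normals <- function(surface) {
  cpp_vertex_normals(surface$vertices, surface$faces - 1L)
}

# edges of a triangle surface as a 2-column matrix (each undirected edge once)
surface_edges <- function(surface) {
  f <- surface$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(e[, 1] * (nrow(surface$vertices) + 1) + e[, 2]), , drop = FALSE]
}

# vertices on the surface boundary (incident to an edge used by one face only)
surface_boundary_vertices <- function(surface) {
  f <- surface$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- pmin(e[, 1], e[, 2]) * (nrow(surface$vertices) + 1) + pmax(e[, 1], e[, 2])
  once <- !(duplicated(key) | duplicated(key, fromLast = TRUE))
  sort(unique(as.vector(e[once, , drop = FALSE])))
}

# check edge-manifoldness: every edge in at most two faces
surface_nonmanifold_edges <- function(surface) {
  f <- surface$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- pmin(e[, 1], e[, 2]) * (nrow(surface$vertices) + 1) + pmax(e[, 1], e[, 2])
  tab <- table(key)
  bad <- as.numeric(names(tab)[tab > 2])
  n <- nrow(surface$vertices) + 1
  if (!length(bad)) return(matrix(0L, 0, 2))
  cbind(as.integer(bad %/% n), as.integer(bad %% n))
}

# per-vertex barycentric area (1/3 of incident face areas)
vertex_areas <- function(surface) {
  v <- surface$vertices; f <- surface$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  fa <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  va <- numeric(nrow(v))
  for (k in 1:3) {
    acc <- tapply(rep(fa / 3, 1), f[, k], sum)
    va[as.integer(names(acc))] <- va[as.integer(names(acc))] + acc
  }
  va
}
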