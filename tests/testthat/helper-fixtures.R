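# Geometric fixtures built in code: analytic triangle surfaces and small
# meshes used as oracles.

# unit sphere by subdivided octahedron, scaled to radius r
make_icosphere <- function(r = 1, subdivisions = 4) {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  for (it in seq_len(subdivisions)) {
    env <- new.env()
    newf <- vector("list", 4 * nrow(f))
    getmid <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      if (!is.null(env[[k]])) return(env[[k]])
      m <- v[a, ] + v[b, ]
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      env[[k]] <- nrow(v)
      nrow(v)
    }
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      ab <- getmid(a, b); bc <- getmid(b, c); ca <- getmid(c, a)
      newf[[4 * t - 3]] <- c(a, ab, ca)
      newf[[4 * t - 2]] <- c(ab, b, bc)
      newf[[4 * t - 1]] <- c(ca, bc, c)
      newf[[4 * t]] <- c(ab, bc, ca)
    }
    f <- do.call(rbind, newf)
  }
  scutefold:::new_tri_surface(r * v, f)
}

# regular-grid height-field sheet z = fz(x, y), outward normal ~ +z
make_sheet <- function(xs, ys, fz) {
  g <- as.matrix(expand.grid(x = xs, y = ys))
  z <- fz(g[, 1], g[, 2])
  idx <- matrix(seq_len(nrow(g)), length(xs), length(ys))
  fcs <- vector("list", 2 * (length(xs) - 1) * (length(ys) - 1))
  k <- 0
  for (j in seq_len(length(ys) - 1)) for (i in seq_len(length(xs) - 1)) {
    fcs[[k + 1]] <- c(idx[i, j], idx[i + 1, j], idx[i + 1, j + 1])
    fcs[[k + 2]] <- c(idx[i, j], idx[i + 1, j + 1], idx[i, j + 1])
    k <- k + 2
  }
  scutefold:::new_tri_surface(cbind(g, z), do.call(rbind, fcs))
}

# open cylinder of radius r about the z axis, outward normals
make_cylinder <- function(r = 5, len = 20, n_circ = 64, n_len = 30) {
  th <- 2 * pi * (seq_len(n_circ) - 1) / n_circ
  zs <- seq(0, len, length.out = n_len)
  verts <- do.call(rbind, lapply(zs, function(z) {
    cbind(r * cos(th), r * sin(th), z)
  }))
  id <- function(i, j) (j - 1L) * n_circ + i         # i circumferential, j axial
  fcs <- vector("list", 2 * n_circ * (n_len - 1))
  k <- 0
  for (j in seq_len(n_len - 1)) for (i in seq_len(n_circ)) {
    i2 <- i %% n_circ + 1
    fcs[[k + 1]] <- c(id(i, j), id(i2, j), id(i2, j + 1))
    fcs[[k + 2]] <- c(id(i, j), id(i2, j + 1), id(i, j + 1))
    k <- k + 2
  }
  scutefold:::new_tri_surface(verts, do.call(rbind, fcs))
}

# fibonacci-lattice oriented point cloud on a sphere
make_sphere_cloud <- function(n = 20000, r = 20, center = c(30, 30, 30)) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  u <- cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
  structure(list(points = sweep(r * u, 2, center, "+"), normals = u),
            class = "oriented_point_cloud")
}

# random well-shaped reference tet (positive volume above a floor)
random_tet <- function() {
  repeat {
    X <- matrix(rnorm(12), 4, 3)
    v <- det(cbind(X[2, ] - X[1, ], X[3, ] - X[1, ], X[4, ] - X[1, ])) / 6
    if (v > 0.05) return(X)
  }
}

# the desk-scale dome used by the folding acceptance runs; documented in the
# methods vignette (defaults of make_layered_cap with the survey spacing)
desk_cap <- function(seed, ...) {
  make_layered_cap(seed = seed, ...)
}
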