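#' @useDynLib scutefold, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm median quantile sd fft nextn lm coef dist
#' @importFrom utils write.csv read.csv
NULL

# ---------------------------------------------------------------------------
# Layered tetrahedral meshes
#
# All lengths are dimensionless: 1 length unit = the initial epidermis
# thickness. Node coordinates are reference (undeformed) geometry.
# ---------------------------------------------------------------------------

new_layered_mesh <- function(nodes, tets, layer, surface_normal, boundary_tags,
                             constraint_n1 = NULL, constraint_n2 = NULL,
                             meta = list()) {
  if (is.null(constraint_n1)) constraint_n1 <- matrix(0, nrow(nodes), 3)
  if (is.null(constraint_n2)) constraint_n2 <- matrix(0, nrow(nodes), 3)
  structure(list(
    nodes = nodes, tets = tets, layer = layer,
    surface_normal = surface_normal, boundary_tags = boundary_tags,
    constraint_n1 = constraint_n1, constraint_n2 = constraint_n2,
    meta = meta), class = "layered_mesh")
}

#' @export
print.layered_mesh <- function(x, ...) {
  cat("<layered_mesh>", nrow(x$nodes), "nodes,", nrow(x$tets), "tets\n")
  cat("  layers:", paste(sprintf("%s=%d", names(table(x$layer)), table(x$layer)),
                         collapse = ", "), "\n")
  cat("  tags:  ", paste(sprintf("%s=%d", names(table(x$boundary_tags)),
                                 table(x$boundary_tags)), collapse = ", "), "\n")
  invisible(x)
}

#' Signed volumes of all tetrahedra
#' @param mesh a `layered_mesh`
#' @return numeric vector of signed volumes (positive for valid meshes)
#' @export
tet_volumes <- function(mesh) {
  p <- mesh$nodes
  t <- mesh$tets
  a <- p[t[, 2], , drop = FALSE] - p[t[, 1], , drop = FALSE]
  b <- p[t[, 3], , drop = FALSE] - p[t[, 1], , drop = FALSE]
  d <- p[t[, 4], , drop = FALSE] - p[t[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
   a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
   a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

#' Validate a layered mesh
#'
#' Checks positive tet orientation, node usage, unit surface normals and
#' tag/layer levels. Stops on violation.
#' @param mesh a `layered_mesh`
#' @return the mesh, invisibly
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "layered_mesh"))
  v <- tet_volumes(mesh)
  if (any(v <= 0))
    stop("mesh has ", sum(v <= 0), " non-positively oriented tetrahedra")
  used <- sort(unique(as.integer(mesh$tets)))
  if (!identical(used, seq_len(nrow(mesh$nodes))))
    stop("mesh has nodes not referenced by any tetrahedron")
  if (!all(mesh$layer %in% c("epidermis", "dermis", "bone")))
    stop("unknown layer labels")
  if (!all(mesh$boundary_tags %in% c("free", "bone_fixed", "lateral")))
    stop("unknown boundary tags")
  nl <- sqrt(rowSums(mesh$surface_normal^2))
  if (any(abs(nl - 1) > 1e-8))
    stop("surface normals are not unit length")
  invisible(mesh)
}

# fix tet orientation in place: swap last two nodes of inverted tets
orient_tets <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  d <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  v <- a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
       a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
       a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])
  flip <- v < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  tets
}

# conforming prism -> 3 tets split; diagonal through smallest global vertex id
# bot/top: integer vectors length 3, top[i] above bot[i]
split_prism <- function(bot, top) {
  ids <- c(bot, top)
  if (which.min(ids) > 3) {          # global min on top: flip prism over
    tmp <- bot
    bot <- top[c(1, 3, 2)]
    top <- tmp[c(1, 3, 2)]
    ids <- c(bot, top)
  }
  r <- which.min(bot) - 1            # rotate min to position 1
  rot <- ((0:2 + r) %% 3) + 1
  u <- bot[rot]; v <- top[rot]
  # third quad (u2, u3, v3, v2): diagonal through its smallest vertex
  quad <- c(u[2], u[3], v[3], v[2])
  if (which.min(quad) %in% c(1, 3)) {   # diagonal u2 - v3
    rbind(c(u[1], u[2], u[3], v[3]),
          c(u[1], u[2], v[3], v[2]),
          c(u[1], v[2], v[3], v[1]))
  } else {                              # diagonal u3 - v2
    rbind(c(u[1], u[2], u[3], v[2]),
          c(u[1], v[2], u[3], v[3]),
          c(u[1], v[2], v[3], v[1]))
  }
}

# triangulated unit disc with hexagonal ring topology; returns polar coords
# (rho in [0,1], phi) and 1-based CCW triangles
disc_triangulation <- function(nrings) {
  rho <- 0; phi <- 0
  ring_start <- integer(nrings + 1)
  ring_start[1] <- 1
  for (i in seq_len(nrings)) {
    ring_start[i + 1] <- ring_start[i] + if (i == 1) 1 else 6 * (i - 1)
  }
  for (i in seq_len(nrings)) {
    n <- 6 * i
    ang <- 2 * pi * (seq_len(n) - 1) / n
    rho <- c(rho, rep(i / nrings, n))
    phi <- c(phi, ang)
  }
  idx_ring <- function(i) {
    if (i == 0) return(1L)
    st <- 2L + 3L * i * (i - 1L)
    st:(st + 6L * i - 1L)
  }
  tris <- list()
  # apex fan
  r1 <- idx_ring(1)
  for (k in 1:6) tris[[length(tris) + 1]] <- c(1L, r1[k], r1[k %% 6 + 1])
  # annuli via two-pointer merge by angle
  for (i in 2:nrings) {
    inner <- idx_ring(i - 1); outer <- idx_ring(i)
    nin <- length(inner); nout <- length(outer)
    ki <- 0L; ko <- 0L
    while (ki < nin || ko < nout) {
      a_in <- if (ki < nin) (ki + 1) / nin else Inf
      a_out <- if (ko < nout) (ko + 1) / nout else Inf
      if (a_out <= a_in) {
        tris[[length(tris) + 1]] <- c(inner[ki %% nin + 1], outer[ko %% nout + 1],
                                      outer[(ko + 1) %% nout + 1])
        ko <- ko + 1L
      } else {
        tris[[length(tris) + 1]] <- c(inner[ki %% nin + 1], outer[ko %% nout + 1],
                                      inner[(ki + 1) %% nin + 1])
        ki <- ki + 1L
      }
    }
  }
  tris <- do.call(rbind, tris)
  # enforce CCW orientation in the (x, y) parameter plane
  x <- rho * cos(phi); y <- rho * sin(phi)
  cr <- (x[tris[, 2]] - x[tris[, 1]]) * (y[tris[, 3]] - y[tris[, 1]]) -
        (y[tris[, 2]] - y[tris[, 1]]) * (x[tris[, 3]] - x[tris[, 1]])
  flip <- cr < 0
  tris[flip, c(2, 3)] <- tris[flip, c(3, 2)]
  list(rho = rho, phi = phi, tris = tris)
}

#' Default spherical-cap geometry
#'
#' The configuration emulating the central dorsal head region: a gently
#' curved dome whose radius is two hundred epidermis thicknesses (the head is
#' large against the skin) and whose arc hosts a handful of fold wavelengths.
#' 1 length unit = initial epidermis thickness. The jitter amplitude (5% of
#' the epidermis thickness) is the symmetry-breaking fluctuation needed to
#' nucleate the subcritical creasing instability.
#' @return named list of `make_layered_cap()` defaults
#' @export
cap_defaults <- function() {
  list(cap_radius = 200, h_epid = 1, h_dermis = 5, h_bone = 1,
       theta_max = 0.13, resolution = 2, lateral_spacing = 1.6,
       perturb_amplitude = 0.05)
}

#' Generate a layered spherical-cap mesh
#'
#' Three concentric layers (bone innermost, then dermis, then epidermis)
#' forming a dome, the synthetic stand-in for the central dorsal head region.
#' Bone nodes are tagged `bone_fixed`, rim nodes `lateral` (constrained
#' against escaping through the cut cone, sliding allowed), the outer surface
#' `free`. Free and lateral node positions are jittered by seeded uniform
#' noise to break symmetry.
#'
#' @param cap_radius outer radius of the epidermis surface
#' @param h_epid,h_dermis,h_bone layer thicknesses (epidermis thickness is the
#'   length unit, so `h_epid = 1` by convention)
#' @param resolution element layers across each skin layer (>= 2)
#' @param perturb_amplitude uniform node jitter amplitude
#' @param seed integer seed for the jitter
#' @param theta_max polar half-angle of the cap
#' @param lateral_spacing target in-surface element edge length
#' @param dermis_layers element layers across the dermis (default
#'   `resolution`; creasing into the dermis needs its through-thickness
#'   deformation resolved, so more layers than the thin epidermis may be
#'   warranted)
#' @return a `layered_mesh`
#' @export
make_layered_cap <- function(cap_radius = 200, h_epid = 1, h_dermis = 5,
                             resolution = 2, perturb_amplitude = 0.05,
                             seed = 1L, theta_max = 0.13, h_bone = 1,
                             lateral_spacing = 1.6, dermis_layers = resolution) {
  if (h_epid <= 0 || h_dermis <= 0 || h_bone <= 0)
    stop("degenerate geometry: all layer thicknesses must be positive")
  if (cap_radius <= h_epid + h_dermis)
    stop("degenerate geometry: cap_radius must exceed h_epid + h_dermis")
  if (resolution < 2 || dermis_layers < 2)
    stop("resolution must be >= 2 element layers per layer")
  if (perturb_amplitude < 0) stop("perturb_amplitude must be >= 0")

  R_out <- cap_radius
  R_ed <- R_out - h_epid            # epidermis-dermis interface
  R_db <- R_ed - h_dermis           # dermis-bone interface
  R_in <- R_db - h_bone
  if (R_in <= 0) stop("degenerate geometry: bone layer reaches the origin")

  nrings <- max(3L, round(R_out * theta_max / lateral_spacing))
  disc <- disc_triangulation(nrings)
  nd <- length(disc$rho)

  radii <- c(R_in, R_db,
             R_db + h_dermis * seq_len(dermis_layers) / dermis_layers,
             R_ed + h_epid * seq_len(resolution) / resolution)
  nl <- length(radii)
  layer_of_gap <- c("bone", rep("dermis", dermis_layers),
                    rep("epidermis", resolution))

  theta <- disc$rho * theta_max
  dirx <- sin(theta) * cos(disc$phi)
  diry <- sin(theta) * sin(disc$phi)
  dirz <- cos(theta)
  nodes <- matrix(0, nd * nl, 3)
  for (l in seq_len(nl)) {
    idx <- (l - 1) * nd + seq_len(nd)
    nodes[idx, 1] <- radii[l] * dirx
    nodes[idx, 2] <- radii[l] * diry
    nodes[idx, 3] <- radii[l] * dirz
  }
  nid <- function(l, d) (l - 1L) * nd + d

  ntri <- nrow(disc$tris)
  tets <- matrix(0L, ntri * (nl - 1) * 3, 4)
  layer <- character(nrow(tets))
  row <- 1L
  for (l in seq_len(nl - 1)) {
    for (t in seq_len(ntri)) {
      tri <- disc$tris[t, ]
      tt <- split_prism(nid(l, tri), nid(l + 1L, tri))
      tets[row:(row + 2L), ] <- tt
      layer[row:(row + 2L)] <- layer_of_gap[l]
      row <- row + 3L
    }
  }
  tets <- orient_tets(nodes, tets)
  storage.mode(tets) <- "integer"

  # per-tet reference surface normal: radial direction at the centroid
  cen <- (nodes[tets[, 1], ] + nodes[tets[, 2], ] +
          nodes[tets[, 3], ] + nodes[tets[, 4], ]) / 4
  nrm <- cen / sqrt(rowSums(cen^2))

  # boundary tags
  r_node <- sqrt(rowSums(nodes^2))
  tags <- rep("free", nrow(nodes))
  tags[r_node <= R_db + 1e-9] <- "bone_fixed"
  rim <- rep(abs(disc$rho - 1) < 1e-12, nl)
  tags[rim & tags != "bone_fixed"] <- "lateral"

  # lateral constraint: no escape through the cut cone (normal = e_theta);
  # sliding within the cut surface (thickening, azimuthal) stays free
  cn1 <- matrix(0, nrow(nodes), 3)
  cn2 <- matrix(0, nrow(nodes), 3)
  lat <- which(tags == "lateral")
  th <- rep(theta, nl)[lat]; ph <- rep(disc$phi, nl)[lat]
  cn1[lat, ] <- cbind(cos(th) * cos(ph), cos(th) * sin(ph), -sin(th))

  # symmetry-breaking jitter (seeded); bone untouched, lateral in-plane only.
  # Outer-surface nodes are jittered tangentially only, so the reference free
  # surface stays smooth and measured curvature reflects folds, not noise.
  if (perturb_amplitude > 0) {
    jit <- local_seed(seed, {
      matrix(runif(3 * nrow(nodes), -perturb_amplitude, perturb_amplitude),
             ncol = 3)
    })
    jit[tags == "bone_fixed", ] <- 0
    jit <- jit - rowSums(jit * cn1) * cn1
    jit <- jit - rowSums(jit * cn2) * cn2
    on_outer <- r_node >= R_out - 1e-9
    rad_dir <- nodes / pmax(r_node, 1e-12)
    jr <- rowSums(jit * rad_dir)
    jit[on_outer, ] <- jit[on_outer, , drop = FALSE] -
      jr[on_outer] * rad_dir[on_outer, , drop = FALSE]
    nodes <- nodes + jit
  }
  mesh <- new_layered_mesh(nodes, tets, layer, nrm, tags, cn1, cn2,
                           meta = list(kind = "cap", cap_radius = cap_radius,
                                       h_epid = h_epid, h_dermis = h_dermis,
                                       h_bone = h_bone, theta_max = theta_max,
                                       resolution = resolution,
                                       lateral_spacing = lateral_spacing,
                                       perturb_amplitude = perturb_amplitude,
                                       seed = seed))
  validate_mesh(mesh)
}

#' Analytic volume of the cap shell sector
#'
#' Closed-form volume of the full three-layer spherical shell sector of a cap
#' mesh: `Omega/3 * (R_out^3 - R_in^3)` with `Omega = 2*pi*(1 - cos(theta_max))`.
#' @param mesh a cap `layered_mesh`
#' @return volume in mesh length units cubed
#' @export
cap_analytic_volume <- function(mesh) {
  m <- mesh$meta
  stopifnot(identical(m$kind, "cap"))
  R_out <- m$cap_radius
  R_in <- R_out - m$h_epid - m$h_dermis - m$h_bone
  omega <- 2 * pi * (1 - cos(m$theta_max))
  omega / 3 * (R_out^3 - R_in^3)
}

# structured triangulated-extrusion box; shared by the bilayer generator
# zlevels: increasing z coordinates of node sheets
box_mesh_core <- function(lx, ly, zlevels, spacing) {
  nx <- max(2L, as.integer(round(lx / spacing)) + 1L)
  ny <- max(2L, as.integer(round(ly / spacing)) + 1L)
  xs <- seq(0, lx, length.out = nx)
  ys <- seq(0, ly, length.out = ny)
  base <- cbind(rep(xs, times = ny), rep(ys, each = nx))
  bid <- function(i, j) (j - 1L) * nx + i
  tris <- list()
  for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1)) {
    q <- c(bid(i, j), bid(i + 1L, j), bid(i + 1L, j + 1L), bid(i, j + 1L))
    if (which.min(q) %in% c(1, 3)) {
      tris[[length(tris) + 1]] <- q[c(1, 2, 3)]
      tris[[length(tris) + 1]] <- q[c(1, 3, 4)]
    } else {
      tris[[length(tris) + 1]] <- q[c(1, 2, 4)]
      tris[[length(tris) + 1]] <- q[c(2, 3, 4)]
    }
  }
  tris <- do.call(rbind, tris)
  nb <- nrow(base); nl <- length(zlevels)
  nodes <- matrix(0, nb * nl, 3)
  for (l in seq_len(nl)) {
    idx <- (l - 1) * nb + seq_len(nb)
    nodes[idx, 1:2] <- base
    nodes[idx, 3] <- zlevels[l]
  }
  nid <- function(l, d) (l - 1L) * nb + d
  tets <- matrix(0L, nrow(tris) * (nl - 1) * 3, 4)
  gap <- integer(nrow(tets))
  row <- 1L
  for (l in seq_len(nl - 1)) for (t in seq_len(nrow(tris))) {
    tt <- split_prism(nid(l, tris[t, ]), nid(l + 1L, tris[t, ]))
    tets[row:(row + 2L), ] <- tt
    gap[row:(row + 2L)] <- l
    row <- row + 3L
  }
  tets <- orient_tets(nodes, tets)
  storage.mode(tets) <- "integer"
  list(nodes = nodes, tets = tets, gap = gap, nx = nx, ny = ny, nb = nb)
}

#' Generate a flat film-on-substrate bilayer mesh
#'
#' Rectangular slab with a stiff thin film (labeled epidermis) on a thick
#' substrate (labeled dermis): the classic wrinkling test geometry. The bottom
#' face is `bone_fixed`; vertical sides are `lateral` (pinned against normal
#' escape, tangential sliding allowed).
#'
#' @param lx,ly lateral extent
#' @param h_film,h_substrate layer thicknesses; `h_substrate >= 5 * h_film`
#' @param resolution element layers across the film (>= 2)
#' @param perturb_amplitude uniform node jitter amplitude (seeded)
#' @param seed integer seed
#' @param lateral_spacing target in-plane element edge length
#' @param modulus_contrast nominal film/substrate stiffness ratio used only to
#'   flag (in `meta$warnings`) domains too short to host four wrinkle
#'   wavelengths
#' @return a `layered_mesh`
#' @export
make_flat_bilayer <- function(lx, ly, h_film = 1, h_substrate = 10,
                              resolution = 2, perturb_amplitude = 1e-3,
                              seed = 1L, lateral_spacing = h_film,
                              modulus_contrast = 100) {
  if (h_substrate < 5 * h_film)
    stop("substrate must dwarf the film: h_substrate >= 5 * h_film")
  if (resolution < 2) stop("resolution must be >= 2 element layers per layer")
  n_sub <- max(2L, ceiling(h_substrate / (2 * h_film)))
  zlevels <- c(h_substrate * (0:n_sub) / n_sub,
               h_substrate + h_film * seq_len(resolution) / resolution)
  core <- box_mesh_core(lx, ly, zlevels, lateral_spacing)
  nodes <- core$nodes; tets <- core$tets
  layer <- ifelse(core$gap > n_sub, "epidermis", "dermis")
  nrm <- matrix(rep(c(0, 0, 1), each = nrow(tets)), ncol = 3)
  tags <- rep("free", nrow(nodes))
  tags[abs(nodes[, 3]) < 1e-9] <- "bone_fixed"
  onx <- abs(nodes[, 1]) < 1e-9 | abs(nodes[, 1] - lx) < 1e-9
  ony <- abs(nodes[, 2]) < 1e-9 | abs(nodes[, 2] - ly) < 1e-9
  side <- (onx | ony) & tags != "bone_fixed"
  tags[side] <- "lateral"
  cn1 <- matrix(0, nrow(nodes), 3)
  cn2 <- matrix(0, nrow(nodes), 3)
  cn1[onx & side, 1] <- 1
  cn1[ony & side & !onx, 2] <- 1
  cn2[onx & ony & side, 2] <- 1
  if (perturb_amplitude > 0) {
    jit <- local_seed(seed, {
      matrix(runif(3 * nrow(nodes), -perturb_amplitude, perturb_amplitude),
             ncol = 3)
    })
    jit[tags == "bone_fixed", ] <- 0
    jit <- jit - rowSums(jit * cn1) * cn1
    jit <- jit - rowSums(jit * cn2) * cn2
    nodes <- nodes + jit
  }
  lam_exp <- 2 * pi * h_film * (modulus_contrast / 3)^(1 / 3)
  warnings <- character(0)
  if (lx < 4 * lam_exp)
    warnings <- sprintf("lx = %g is below 4 expected wrinkle wavelengths (%g)",
                        lx, 4 * lam_exp)
  mesh <- new_layered_mesh(nodes, tets, layer, nrm, tags, cn1, cn2,
                           meta = list(kind = "bilayer", lx = lx, ly = ly,
                                       h_film = h_film,
                                       h_substrate = h_substrate,
                                       resolution = resolution,
                                       lateral_spacing = lateral_spacing,
                                       perturb_amplitude = perturb_amplitude,
                                       seed = seed, warnings = warnings))
  validate_mesh(mesh)
}

#' Generate an unconstrained single-layer box mesh
#'
#' A free-floating block with no fixed or lateral boundaries, used for
#' free-growth and uniaxial benchmarks.
#' @param lx,ly,lz box dimensions
#' @param spacing target element edge length
#' @param layer layer label for all elements
#' @param normal growth-direction unit normal shared by all elements
#' @return a `layered_mesh`
#' @export
make_free_box <- function(lx = 1, ly = 1, lz = 1, spacing = 0.5,
                          layer = "dermis", normal = c(0, 0, 1)) {
  nzl <- max(2L, round(lz / spacing))
  core <- box_mesh_core(lx, ly, seq(0, lz, length.out = nzl + 1), spacing)
  nrm <- matrix(rep(normal / sqrt(sum(normal^2)), each = nrow(core$tets)),
                ncol = 3)
  mesh <- new_layered_mesh(core$nodes, core$tets,
                           rep(layer, nrow(core$tets)), nrm,
                           rep("free", nrow(core$nodes)),
                           meta = list(kind = "box", lx = lx, ly = ly, lz = lz))
  validate_mesh(mesh)
}

#' Boundary triangles of a tetrahedral mesh
#'
#' Faces belonging to exactly one tetrahedron, oriented outward.
#' @param mesh a `layered_mesh`
#' @param free_only keep only faces whose three nodes are not `bone_fixed`
#' @return integer matrix of 1-based vertex triples
#' @export
boundary_faces <- function(mesh, free_only = FALSE) {
  t <- mesh$tets
  faces <- rbind(t[, c(1, 3, 2)], t[, c(1, 2, 4)], t[, c(2, 3, 4)], t[, c(1, 4, 3)])
  n <- nrow(mesh$nodes) + 1
  s1 <- pmin(faces[, 1], faces[, 2], faces[, 3])
  s3 <- pmax(faces[, 1], faces[, 2], faces[, 3])
  s2 <- faces[, 1] + faces[, 2] + faces[, 3] - s1 - s3
  key <- (s1 * n + s2) * n + s3      # exact for n^3 < 2^53
  keep <- !(duplicated(key) | duplicated(key, fromLast = TRUE))
  faces <- faces[keep, , drop = FALSE]
  # orient outward: normal . (face centroid - tet centroid) > 0
  tet_of <- rep(seq_len(nrow(t)), 4)[keep]
  tc <- (mesh$nodes[t[tet_of, 1], ] + mesh$nodes[t[tet_of, 2], ] +
         mesh$nodes[t[tet_of, 3], ] + mesh$nodes[t[tet_of, 4], ]) / 4
  fc <- (mesh$nodes[faces[, 1], ] + mesh$nodes[faces[, 2], ] +
         mesh$nodes[faces[, 3], ]) / 3
  e1 <- mesh$nodes[faces[, 2], ] - mesh$nodes[faces[, 1], ]
  e2 <- mesh$nodes[faces[, 3], ] - mesh$nodes[faces[, 1], ]
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  dp <- nx * (fc[, 1] - tc[, 1]) + ny * (fc[, 2] - tc[, 2]) + nz * (fc[, 3] - tc[, 3])
  flip <- dp < 0
  faces[flip, c(2, 3)] <- faces[flip, c(3, 2)]
  if (free_only) {
    tag <- mesh$boundary_tags
    ok <- tag[faces[, 1]] != "bone_fixed" & tag[faces[, 2]] != "bone_fixed" &
          tag[faces[, 3]] != "bone_fixed"
    faces <- faces[ok, , drop = FALSE]
  }
  faces
}

#' Extract the deformed free surface as a triangle surface
#'
#' @param mesh a `layered_mesh`
#' @param positions current nodal positions (defaults to reference)
#' @return a `tri_surface` over the free boundary (vertices re-indexed)
#' @export
free_surface <- function(mesh, positions = mesh$nodes) {
  faces <- boundary_faces(mesh, free_only = TRUE)
  tag <- mesh$boundary_tags
  keep <- tag[faces[, 1]] == "free" & tag[faces[, 2]] == "free" &
          tag[faces[, 3]] == "free"
  faces <- faces[keep, , drop = FALSE]
  verts_used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(mesh$nodes))
  remap[verts_used] <- seq_along(verts_used)
  new_tri_surface(positions[verts_used, , drop = FALSE],
                  matrix(remap[faces], ncol = 3),
                  meta = list(source_nodes = verts_used))
}

# evaluate expr under a local RNG seed, restoring the caller's RNG state
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
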