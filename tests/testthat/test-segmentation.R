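# Volumetric segmentation: edges, normals, reconstruction, thickness, cells.

test_that("a constant stack yields no edges, and edges localize on the phantom surfaces", {
  flat <- array(0.5, c(24, 24, 24))
  expect_equal(sum(canny_edges_3d(flat)), 0)

  p <- make_image_phantom(n_cells = 0, noise_sd = 0, seed = 1)
  e <- canny_edges_3d(p$stack)
  pts <- mask_to_points(e)
  ctr <- p$truth_outer_surface$center
  r <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  R_out <- p$truth_outer_surface$radius
  R_in <- p$truth_inner_surface$radius
  R_db <- R_in - p$meta$h_dermis
  # every edge voxel lies within 1 voxel of one of the analytic interfaces
  dmin <- pmin(abs(r - R_out), abs(r - R_in), abs(r - R_db))
  expect_lt(quantile(dmin, 0.99), 1)
  # both skin surfaces are represented
  expect_gt(sum(abs(r - R_out) < 1), 100)
  expect_gt(sum(abs(r - R_in) < 1), 100)
  # the nested surfaces split into >= 2 connected components
  lab <- label_components_3d(e)
  expect_gte(max(lab), 2)
})

test_that("canny edge detection is equivariant under axis permutations", {
  p <- make_image_phantom(shape = c(40, 40, 32), h_epid = 3, h_dermis = 7,
                          n_cells = 0, noise_sd = 0, seed = 1)
  e <- canny_edges_3d(p$stack)
  perm <- c(3, 1, 2)
  e_perm <- canny_edges_3d(aperm(p$stack, perm))
  expect_equal(unname(aperm(e, perm)), unname(e_perm))
})

test_that("gradient normals are radial on a spherical field, antisymmetric, and axis-exact on a step", {
  # smooth radial field: intensity decreasing with radius -> outward normals
  d <- c(32, 32, 32); ctr <- (d - 1) / 2
  xs <- (0:(d[1] - 1)) - ctr[1]
  r <- sqrt(outer(outer(xs^2, xs^2, "+"), xs^2, "+"))
  stack <- exp(-(r / 10)^2)
  pts <- mask_to_points(r > 6 & r < 9)
  cl <- estimate_normals(stack, pts, sigma = 1)
  radial <- sweep(cl$points, 2, ctr)
  radial <- radial / sqrt(rowSums(radial^2))
  ang <- acos(pmin(1, rowSums(cl$normals * radial)))
  expect_lt(max(ang) * 180 / pi, 2)
  # sign flip of the stack negates all normals
  cl2 <- estimate_normals(-stack, pts, sigma = 1)
  expect_equal(cl2$normals, -cl$normals, tolerance = 1e-12)
  # flat step along z -> normals exactly +/- z
  step <- array(0, c(16, 16, 16))
  step[, , 1:8] <- 1
  spts <- cbind(rep(4:11, each = 4), rep(4:11, length.out = 32), 7)
  cls <- estimate_normals(step, spts, sigma = 1)
  expect_true(all(abs(cls$normals[, 3]) == 1))
  expect_true(all(cls$normals[, 1:2] == 0))
})

test_that("surface reconstruction meets the area, Hausdorff and compression contracts", {
  cloud <- make_sphere_cloud(n = 20000, r = 20)
  s <- reconstruct_surface(cloud, spacing = 2)
  # lighter format: far fewer vertices than input points
  expect_lt(nrow(s$vertices), 0.5 * nrow(cloud$points))
  expect_equal(surface_area(s), 4 * pi * 400, tolerance = 0.05)
  d <- scutefold:::cpp_min_dist_points(s$vertices, cloud$points)
  expect_lt(max(d), 1)
  # planar cloud: all vertices within tolerance of the plane
  g <- as.matrix(expand.grid(x = seq(0, 30, 0.75), y = seq(0, 30, 0.75)))
  pc <- structure(list(points = cbind(g, 10),
                       normals = matrix(rep(c(0, 0, 1), nrow(g)), ncol = 3,
                                        byrow = TRUE)),
                  class = "oriented_point_cloud")
  sp <- reconstruct_surface(pc, spacing = 1.5)
  expect_lt(max(abs(sp$vertices[, 3] - 10)), 0.5)
  # too-few points and incoherent orientations are rejected
  expect_error(reconstruct_surface(structure(list(points = g[1:50, , drop = FALSE],
                                                  normals = g[1:50, , drop = FALSE]),
                                             class = "oriented_point_cloud")),
               "100")
  scr <- cloud
  withr::with_seed(1, {
    flip <- sample(c(-1, 1), nrow(scr$normals), replace = TRUE)
  })
  scr$normals <- scr$normals * flip
  expect_error(reconstruct_surface(scr, spacing = 2), "re-orient")
})

test_that("thickness mapping: concentric spheres, coincident surfaces and parallel planes", {
  outer_s <- make_icosphere(20, 4)
  inner_s <- make_icosphere(15, 4)
  th <- thickness_map(outer_s, inner_s)
  expect_true(all(abs(th - 5) < 0.5))
  # coincident surfaces -> zero thickness
  th0 <- thickness_map(outer_s, outer_s)
  expect_lt(max(th0), 1e-6)
  # parallel planes gap g -> thickness exactly g
  up <- make_sheet(seq(0, 10, 0.5), seq(0, 10, 0.5), function(x, y) rep(3, length(x)))
  dn <- make_sheet(seq(-2, 12, 0.5), seq(-2, 12, 0.5), function(x, y) rep(0, length(x)))
  thp <- thickness_map(up, dn)
  expect_equal(unname(as.vector(thp)), rep(3, nrow(up$vertices)), tolerance = 1e-9)
})

test_that("cell detection finds exactly the planted blobs with subvoxel centroids", {
  p <- make_image_phantom(n_cells = 20, noise_sd = 0, seed = 3)
  det <- detect_cells(p$cell_stack, scale = 1.5)
  expect_equal(nrow(det$centroids), 20)
  d <- scutefold:::cpp_min_dist_points(p$truth_cells, det$centroids)
  expect_lt(max(d), 1)
  # zero stack -> no detections
  expect_equal(nrow(detect_cells(array(0, c(16, 16, 16)))$centroids), 0)
  # two blobs at 2.5x radius separation stay resolved
  two <- array(0, c(40, 20, 20))
  ctrs <- rbind(c(12, 10, 10), c(12 + 2.5 * 3, 10, 10))
  xs <- 0:39; ys <- 0:19; zs <- 0:19
  for (i in 1:2) {
    d2 <- outer(outer((xs - ctrs[i, 1])^2, (ys - ctrs[i, 2])^2, "+"),
                (zs - ctrs[i, 3])^2, "+")
    two <- two + 0.5 * exp(-d2 / (2 * 1.5^2))
  }
  det2 <- detect_cells(two, scale = 1.5)
  expect_equal(nrow(det2$centroids), 2)
  expect_lt(max(scutefold:::cpp_min_dist_points(ctrs, det2$centroids)), 1)
})

test_that("per-layer densities: disjointness, scaling, missing masks and Poisson homogeneity", {
  d <- c(40, 40, 40)
  maskA <- array(FALSE, d); maskA[1:40, , 1:20] <- TRUE
  maskB <- array(FALSE, d); maskB[1:40, , 21:40] <- TRUE
  cells <- structure(list(centroids = cbind(runif(0), runif(0), runif(0)),
                          scores = numeric(0)), class = "cell_detection")
  # all cells in one layer -> zero density in the other
  withr::with_seed(2, {
    pts <- cbind(runif(400, 0, 39), runif(400, 0, 39), runif(400, 0, 18))
  })
  cells$centroids <- pts
  tab <- proliferation_density(cells, list(epidermis = maskA, dermis = maskB))
  expect_equal(tab$n_cells[tab$layer == "epidermis"], 400)
  expect_equal(tab$density[tab$layer == "dermis"], 0)
  # doubling the mask volume with the same cells halves the density
  half <- array(FALSE, d); half[1:40, 1:20, 1:20] <- TRUE
  sub <- cells
  sub$centroids <- pts[pts[, 2] < 19, , drop = FALSE]
  t2 <- proliferation_density(sub, list(a = half))
  t2b <- proliferation_density(sub, list(a = maskA))
  expect_equal(t2b$n_cells[1], t2$n_cells[1])
  expect_equal(t2b$density[1] / t2$density[1], 0.5, tolerance = 1e-9)
  # uniform (Poisson-like) cells: binned CV within 3 sigma of 1/sqrt(mean)
  t3 <- proliferation_density(cells, list(a = maskA))
  cvp <- t3$cv_poisson[1]
  expect_lt(abs(t3$cv_binned[1] - cvp), 3 * cvp / sqrt(2 * 7))
  # empty mask reported as missing, overlap rejected
  empty <- array(FALSE, d)
  te <- proliferation_density(cells, list(none = empty))
  expect_true(is.na(te$density[1]))
  expect_error(proliferation_density(cells, list(a = maskA, b = maskA)),
               "disjoint")
})

test_that("end-to-end segmentation recovers the epidermis thickness and both surfaces", {
  p <- make_image_phantom(h_epid = 4, h_dermis = 12, n_cells = 0,
                          noise_sd = 0, seed = 1)
  seg <- segment_skin_surfaces(p$stack)
  expect_lt(nrow(seg$outer$vertices), sum(seg$edges))
  th <- thickness_map(seg$outer, seg$inner)
  expect_lt(abs(mean(th) - p$meta$h_epid), 1)
})
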