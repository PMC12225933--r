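# Synthetic layered meshes: validity invariants, determinism, geometry.

test_that("layered cap is valid, deterministic at zero noise, and matches the analytic shell volume", {
  m <- make_layered_cap(cap_radius = 30, h_epid = 1, h_dermis = 5,
                        resolution = 2, perturb_amplitude = 0, seed = 1,
                        theta_max = pi / 3, lateral_spacing = 1.2)
  expect_s3_class(m, "layered_mesh")
  v <- tet_volumes(m)
  expect_true(all(v > 0))
  # zero-noise output is seed-invariant, bit for bit
  m2 <- make_layered_cap(cap_radius = 30, h_epid = 1, h_dermis = 5,
                         resolution = 2, perturb_amplitude = 0, seed = 999,
                         theta_max = pi / 3, lateral_spacing = 1.2)
  expect_identical(m$nodes, m2$nodes)
  expect_identical(m$tets, m2$tets)
  # closed-form spherical-shell sector volume
  expect_lt(abs(sum(v) - cap_analytic_volume(m)) / cap_analytic_volume(m), 0.02)
})

test_that("cap element quality: epidermis tet circumradii stay below every layer thickness", {
  m <- make_layered_cap(cap_radius = 30, h_epid = 1, h_dermis = 5,
                        resolution = 2, perturb_amplitude = 0, seed = 1,
                        lateral_spacing = 1)
  ep <- which(m$layer == "epidermis")
  # circumradius from the circumscribed sphere of each tet
  circum <- vapply(ep, function(e) {
    p <- m$nodes[m$tets[e, ], ]
    A <- 2 * (p[2:4, ] - matrix(p[1, ], 3, 3, byrow = TRUE))
    b <- rowSums(p[2:4, ]^2) - sum(p[1, ]^2)
    ctr <- solve(A, b)
    sqrt(sum((ctr - p[1, ])^2))
  }, 0)
  expect_true(all(circum < 1))     # min layer thickness (h_epid = 1)
})

test_that("cap boundary tags partition nodes as built", {
  m <- make_layered_cap(perturb_amplitude = 0, seed = 1)
  r <- sqrt(rowSums(m$nodes^2))
  R_db <- m$meta$cap_radius - m$meta$h_epid - m$meta$h_dermis
  expect_true(all(m$boundary_tags[r <= R_db + 1e-9] == "bone_fixed"))
  expect_true(all(m$boundary_tags %in% c("free", "bone_fixed", "lateral")))
  expect_gt(sum(m$boundary_tags == "lateral"), 0)
  # lateral constraint normals are unit length
  lat <- m$boundary_tags == "lateral"
  expect_true(all(abs(sqrt(rowSums(m$constraint_n1[lat, ]^2)) - 1) < 1e-9))
})

test_that("flat bilayer has the constructed dimensions, film layering and seeded-noise contract", {
  b0 <- make_flat_bilayer(lx = 40, ly = 40, h_film = 1, h_substrate = 10,
                          resolution = 2, perturb_amplitude = 0, seed = 1)
  bb <- apply(b0$nodes, 2, max) - apply(b0$nodes, 2, min)
  expect_equal(bb, c(40, 40, 11))
  # exactly 2 element layers span the film in z
  zf <- sort(unique(b0$nodes[b0$nodes[, 3] > 10 - 1e-9, 3]))
  expect_equal(zf, c(10, 10.5, 11))
  expect_true(all(tet_volumes(b0) > 0))
  # different seeds: same connectivity, different node sets
  b1 <- make_flat_bilayer(lx = 40, ly = 40, h_film = 1, h_substrate = 10,
                          resolution = 2, perturb_amplitude = 1e-3, seed = 1)
  b2 <- make_flat_bilayer(lx = 40, ly = 40, h_film = 1, h_substrate = 10,
                          resolution = 2, perturb_amplitude = 1e-3, seed = 2)
  expect_identical(b1$tets, b2$tets)
  expect_false(identical(b1$nodes, b2$nodes))
  # film is epidermis, substrate dermis, normals +z
  expect_true(all(b1$surface_normal[, 3] == 1))
  expect_setequal(unique(b1$layer), c("epidermis", "dermis"))
})

test_that("bilayer rejects a thin substrate and warns (in metadata) about short domains", {
  expect_error(make_flat_bilayer(lx = 40, ly = 40, h_film = 1, h_substrate = 3),
               "dwarf")
  b <- make_flat_bilayer(lx = 20, ly = 20, h_film = 1, h_substrate = 10,
                         perturb_amplitude = 0, modulus_contrast = 100)
  expect_true(length(b$meta$warnings) > 0)
})

test_that("degenerate cap geometries are rejected before meshing", {
  expect_error(make_layered_cap(cap_radius = 5, h_epid = 1, h_dermis = 5),
               "degenerate")
  expect_error(make_layered_cap(h_epid = -1), "degenerate")
  expect_error(make_layered_cap(resolution = 1), "resolution")
})

test_that("mesh generators honor the seed: identical seeds give identical meshes", {
  a <- make_layered_cap(seed = 7)
  b <- make_layered_cap(seed = 7)
  expect_identical(a$nodes, b$nodes)
  a2 <- make_layered_cap(seed = 8)
  expect_false(identical(a$nodes, a2$nodes))
})

test_that("boundary faces are outward-oriented and closed for a free box", {
  m <- make_free_box(2, 2, 2, 0.5)
  f <- boundary_faces(m)
  # outward test: face normal dot (centroid - box center) > 0
  ctr <- colMeans(m$nodes)
  e1 <- m$nodes[f[, 2], ] - m$nodes[f[, 1], ]
  e2 <- m$nodes[f[, 3], ] - m$nodes[f[, 1], ]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  fc <- (m$nodes[f[, 1], ] + m$nodes[f[, 2], ] + m$nodes[f[, 3], ]) / 3
  expect_true(all(rowSums(nrm * sweep(fc, 2, ctr)) > 0))
  # total boundary area equals the box surface area
  s <- scutefold:::new_tri_surface(m$nodes, f)
  expect_equal(surface_area(s), 6 * 4, tolerance = 1e-10)
})

test_that("VTK mesh round trip preserves geometry, layers and tags", {
  m <- make_layered_cap(theta_max = 0.08, lateral_spacing = 2.5, seed = 3)
  p <- tempfile(fileext = ".vtk")
  write_vtk_mesh(m, p)
  m2 <- read_vtk_mesh(p)
  expect_equal(m2$nodes, m$nodes, tolerance = 1e-6)
  expect_identical(m2$tets, m$tets)
  expect_identical(m2$layer, m$layer)
  expect_identical(m2$boundary_tags, m$boundary_tags)
  unlink(p)
})
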