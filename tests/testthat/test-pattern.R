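# Fold-pattern quantification: curvature conventions, crease networks,
# domain segmentation, spectral wavelength and species ranking.

test_that("mean curvature follows the documented sign table on analytic surfaces", {
  sph <- make_icosphere(r = 20, subdivisions = 4)
  H <- surface_curvature(sph)
  expect_equal(mean(H), 1 / 20, tolerance = 0.01)      # convex: positive
  expect_lt(sd(H), 0.005)                               # ... and uniform
  flat <- make_sheet(seq(0, 10, 0.5), seq(0, 10, 0.5),
                     function(x, y) rep(0, length(x)))
  expect_lt(max(abs(surface_curvature(flat))), 1e-10)   # plane: zero
  cyl <- make_cylinder(r = 5, len = 20)
  Hc <- surface_curvature(cyl)
  inner <- abs(cyl$vertices[, 3] - 10) < 5              # away from open ends
  expect_equal(mean(abs(Hc[inner])), 1 / 10, tolerance = 0.02)
})

test_that("non-manifold surfaces are rejected with the offending edges", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, -1, 0.2))
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))       # edge 1-2 in 3 faces
  s <- scutefold:::new_tri_surface(v, f)
  expect_error(surface_curvature(s), "non-manifold")
})

test_that("crease extraction: smooth surfaces are empty, a groove is one open path", {
  # smooth cap before growth: adaptive threshold is non-negative -> empty
  m <- make_layered_cap(theta_max = 0.08, lateral_spacing = 2.5, seed = 1,
                        perturb_amplitude = 0)
  s0 <- free_surface(m, m$nodes)
  net0 <- extract_creases(s0)
  expect_equal(net0$n_components, 0)
  expect_equal(net0$total_crease_length, 0)
  # single folded groove across a sheet: one open component spanning it
  groove <- make_sheet(seq(0, 30, 0.5), seq(0, 10, 0.5),
                       function(x, y) -2 * exp(-(x - 15)^2 / 2))
  cg <- surface_curvature(groove)
  netg <- extract_creases(groove, cg, threshold = -0.3)
  expect_equal(netg$n_components, 1)
  expect_true(all(netg$component_open))
  span <- range(groove$vertices[netg$crease_vertices, 2])
  expect_lt(span[1], 1); expect_gt(span[2], 9)
  # crease vertices hug the groove floor
  expect_lt(max(abs(groove$vertices[netg$crease_vertices, 1] - 15)), 1.5)
  # explicit non-negative threshold is a user error
  expect_error(extract_creases(groove, cg, threshold = 0.1), "negative")
})

test_that("a field of isolated domes yields closed crease rings and matching domains", {
  centers <- as.matrix(expand.grid(x = c(10, 25, 40), y = c(10, 25)))
  dome_field <- make_sheet(seq(0, 50, 0.5), seq(0, 35, 0.5), function(x, y) {
    z <- numeric(length(x))
    for (k in seq_len(nrow(centers)))
      z <- z + 3 * exp(-((x - centers[k, 1])^2 + (y - centers[k, 2])^2) / (2 * 2^2))
    z
  })
  cu <- surface_curvature(dome_field)
  net <- extract_creases(dome_field, cu, threshold = -0.05)
  closed <- sum(!net$component_open)
  expect_equal(closed, nrow(centers))
  dom <- segment_domains(dome_field, net)
  # interior domains (dome tops) match the dome count; the surround touches
  # the sheet boundary
  expect_equal(sum(!dom$touches_boundary), nrow(centers))
  # partition property: every non-crease vertex gets exactly one label
  crease <- rep(FALSE, nrow(dome_field$vertices))
  crease[net$crease_vertices] <- TRUE
  expect_true(all(!is.na(dom$labels[!crease])))
  expect_true(all(is.na(dom$labels[crease])))
  # domain areas sum to the total non-crease vertex area
  va <- scutefold:::vertex_areas(dome_field)
  expect_equal(sum(dom$areas), sum(va[!crease]), tolerance = 1e-9)
})

test_that("empty network leaves one domain covering the surface", {
  flat <- make_sheet(seq(0, 10, 0.5), seq(0, 10, 0.5),
                     function(x, y) rep(0, length(x)))
  net <- extract_creases(flat, surface_curvature(flat))
  st <- pattern_statistics(flat, net)
  expect_equal(st$n_domains, 1)
  expect_equal(st$crease_length_density, 0)
})

test_that("dominant wavelength recovers a sinusoid and scales linearly with the surface", {
  lam0 <- 12.5
  sheet <- make_sheet(seq(0, 100, 1), seq(0, 30, 1),
                      function(x, y) 2 * sin(2 * pi * x / lam0))
  wl <- dominant_wavelength(sheet)
  expect_equal(wl, lam0, tolerance = 0.1)
  sheet2 <- sheet
  sheet2$vertices <- 2 * sheet$vertices
  expect_equal(dominant_wavelength(sheet2), 2 * wl, tolerance = 0.02)
})

test_that("pattern statistics are invariant under rigid motions and scale correctly", {
  groove <- make_sheet(seq(0, 30, 0.6), seq(0, 12, 0.6),
                       function(x, y) -2 * exp(-(x - 15)^2 / 2) +
                                       0.5 * sin(2 * pi * y / 6))
  net <- extract_creases(groove, threshold = -0.25)
  st <- pattern_statistics(groove, net)
  # rigid motion: rotate + translate
  th <- 0.62
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Rx <- rbind(c(1, 0, 0), c(0, cos(0.3), -sin(0.3)), c(0, sin(0.3), cos(0.3)))
  g2 <- groove
  g2$vertices <- sweep(groove$vertices %*% t(Rx %*% Rz), 2, c(5, -3, 11), "+")
  net2 <- extract_creases(g2, threshold = -0.25)
  st2 <- pattern_statistics(g2, net2)
  expect_equal(st2$crease_length_density, st$crease_length_density,
               tolerance = 1e-6)
  expect_equal(st2$n_domains, st$n_domains)
  # uniform scaling: lengths linear, areas quadratic
  g3 <- groove
  g3$vertices <- 3 * groove$vertices
  net3 <- extract_creases(g3, threshold = -0.25 / 3)   # curvature scales as 1/L
  expect_equal(net3$total_crease_length, 3 * net$total_crease_length,
               tolerance = 1e-6)
  st3 <- pattern_statistics(g3, net3)
  expect_equal(st3$mean_domain_area, 9 * st$mean_domain_area, tolerance = 1e-6)
})

test_that("species ranking: degenerate ties refuse an ordering, forced orderings reproduce", {
  mk <- function(sp, dens) data.frame(species = sp, seed = seq_along(dens),
                                      crease_length_density = dens)
  tied <- rbind(mk("sulcata", c(1, 2, 3)), mk("graeca", c(1, 2, 3)),
                mk("marginata", c(1, 2, 3)))
  rt <- compare_species(tied)
  expect_true(rt$tie)
  expect_false(isTRUE(rt$matches_expected))
  forced <- rbind(mk("sulcata", c(3, 3.1, 2.9)), mk("graeca", c(2, 2.1, 1.9)),
                  mk("marginata", c(1, 1.1, 0.9)))
  rf <- compare_species(forced)
  expect_identical(rf$ranking, c("sulcata", "graeca", "marginata"))
  expect_true(rf$matches_expected)
  expect_equal(rf$confidence, 1)
  expect_error(compare_species(rbind(mk("sulcata", c(1, 2)), mk("graeca", c(1, 2, 3)))),
               "3 seeds")
})
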