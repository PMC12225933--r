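# Neo-Hookean growth mechanics: parameter tables, element response, contact,
# integrator and simulator invariants.

test_that("species parameter table returns the published rows", {
  s <- species_parameters("sulcata")
  expect_equal(c(s$material$E_epid, s$material$E_dermis), c(3, 1))
  expect_equal(c(s$material$nu_epid, s$material$nu_dermis), c(0.1, 0.4))
  expect_equal(c(s$growth$gT_epid, s$growth$gN_epid), c(0.6, 0))
  expect_equal(c(s$growth$gT_dermis, s$growth$gN_dermis), c(0.6, 0.3))
  g <- species_parameters("graeca")
  expect_equal(c(g$material$E_epid, g$material$nu_epid, g$material$nu_dermis),
               c(2, 0.25, 0.45))
  expect_equal(c(g$growth$gT_epid, g$growth$gT_dermis, g$growth$gN_dermis),
               c(0.5, 0.7, 0.1))
  m <- species_parameters("marginata")
  expect_equal(m$growth$gT_epid, 0.45)
  expect_equal(c(m$material$E_epid, m$growth$gT_dermis), c(2, 0.7))
  expect_error(species_parameters("terrapin"), "sulcata")
})

test_that("Lame conversion matches the closed form and rejects the incompressible limit", {
  expect_equal(lame_parameters(1, 0), c(mu = 0.5, lam = 0))
  # epidermis values of the stiffest parameter set
  l <- lame_parameters(3, 0.1)
  expect_equal(unname(l["mu"]), 3 / 2.2, tolerance = 1e-12)
  expect_equal(unname(l["lam"]), 0.3 / (1.1 * 0.8), tolerance = 1e-12)
  l2 <- lame_parameters(1, 0.45)
  expect_equal(unname(l2["lam"] / l2["mu"]), 9, tolerance = 1e-12)
  expect_error(lame_parameters(1, 0.5), "incompressible")
  expect_error(lame_parameters(-1, 0.3), "positive")
})

test_that("growth tensor has the stated structure and determinant", {
  expect_equal(growth_tensor(c(0, 0, 1), 0, 0), diag(3))
  G <- growth_tensor(c(0, 0, 1), 0.6, 0)
  expect_equal(det(G), 1.6^2, tolerance = 1e-12)
  expect_equal(G, diag(c(1.6, 1.6, 1)))
  G2 <- growth_tensor(c(0, 0, 1), 0.6, 0.3)
  expect_equal(det(G2), 1.6^2 * 1.3, tolerance = 1e-12)
  # symmetric positive definite for a tilted normal
  n <- c(1, 2, 2) / 3
  G3 <- growth_tensor(n, 0.5, -0.2)
  expect_equal(G3, t(G3))
  expect_true(all(eigen(G3, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_error(growth_tensor(c(0, 0, 2), 0.1, 0), "unit")
  expect_error(growth_tensor(c(0, 0, 1), -1.5, 0), "1 \\+ g")
})

test_that("element response vanishes at rest and under compatible free growth", {
  X <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), 4, 3, byrow = TRUE)
  r0 <- element_response(X, X, diag(3), mu = 1.3, lam = 0.7)
  expect_equal(r0$energy, 0)
  expect_equal(max(abs(r0$forces)), 0)
  # current = G applied to reference: F_e = I exactly
  G <- growth_tensor(c(0, 0, 1), 0.6, 0.3)
  r1 <- element_response(X, X %*% t(G), G, mu = 1.3, lam = 0.7)
  expect_lt(abs(r1$energy), 1e-12)
  expect_lt(max(abs(r1$forces)), 1e-12)
})

test_that("analytic element forces match central finite differences on random elements", {
  withr::with_seed(11, {
    worst <- 0
    for (rep in 1:100) {
      X <- random_tet()
      x <- X + 0.1 * matrix(rnorm(12), 4, 3)
      n <- rnorm(3); n <- n / sqrt(sum(n^2))
      G <- growth_tensor(n, runif(1, -0.2, 0.6), runif(1, -0.2, 0.4))
      mu <- runif(1, 0.5, 2); lam <- runif(1, 0, 2)
      r <- tryCatch(element_response(X, x, G, mu, lam), error = function(e) NULL)
      if (is.null(r)) next                       # inverted sample: skip
      h <- 1e-6
      fd <- matrix(0, 4, 3)
      for (a in 1:4) for (c in 1:3) {
        xp <- x; xp[a, c] <- xp[a, c] + h
        xm <- x; xm[a, c] <- xm[a, c] - h
        fd[a, c] <- -(element_response(X, xp, G, mu, lam)$energy -
                      element_response(X, xm, G, mu, lam)$energy) / (2 * h)
      }
      worst <- max(worst, max(abs(fd - r$forces)) / max(abs(r$forces)))
    }
    expect_lt(worst, 1e-6)
  })
})

test_that("element inversion is reported as an error", {
  X <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), 4, 3, byrow = TRUE)
  x <- X; x[4, 3] <- -1       # reflect through the base plane
  expect_error(element_response(X, x, diag(3), 1, 1), "J_e")
})

test_that("uniaxial single-element bar reproduces the closed-form neo-Hookean nominal stress", {
  # nu = 0: lateral stretch stays 1, nominal stress P = mu (s - 1/s)
  m <- make_free_box(1, 1, 1, spacing = 1)
  mat <- material_spec(1, 1, 0, 0)      # mu = 0.5
  mu <- mat$mu_dermis
  gr <- growth_spec(0, 0, 0, 0)
  for (s in c(1.1, 1.5, 2.0)) {
    pos <- m$nodes
    pos[, 1] <- s * pos[, 1]
    f <- elastic_forces(m, pos, mat, gr)$forces
    face <- abs(m$nodes[, 1] - 1) < 1e-9
    P <- sum(f[face, 1])                # reaction on the stretched face (area 1)
    expect_equal(abs(P), mu * (s - 1 / s), tolerance = 1e-6)
  }
})

test_that("contact forces separate overlapping sheets, conserve momentum and vanish at the radius", {
  # two parallel 2-triangle sheets, gap g, plus far-away padding
  sheet <- function(z) cbind(c(0, 2, 2, 0), c(0, 0, 2, 2), rep(z, 4))
  for (g in c(0.2, 0.4, 0.499, 0.5, 0.7)) {
    pos <- rbind(sheet(0), sheet(g))
    tris <- rbind(c(1, 2, 3), c(1, 3, 4), c(5, 6, 7), c(5, 7, 8))
    r <- contact_forces(pos, tris, penalty = 2, radius = 0.5)
    if (g < 0.5) {
      expect_gt(max(abs(r$forces[, 3])), 0)
      # equal and opposite: total momentum flux zero
      expect_lt(max(abs(colSums(r$forces))), 1e-10)
      # repulsion along the sheet normal
      expect_true(all(r$forces[5:8, 3] >= 0))
      expect_true(all(r$forces[1:4, 3] <= 0))
    } else {
      expect_equal(max(abs(r$forces)), 0)
    }
  }
  # continuity: force -> 0 as gap -> radius
  near <- contact_forces(rbind(sheet(0), sheet(0.4999)),
                         rbind(c(1, 2, 3), c(1, 3, 4), c(5, 6, 7), c(5, 7, 8)),
                         penalty = 2, radius = 0.5)
  expect_lt(max(abs(near$forces)), 1e-3)
  # smooth undeformed cap: no self-contact anywhere
  m <- make_layered_cap(theta_max = 0.08, lateral_spacing = 2.5, seed = 1)
  rc <- contact_forces(m$nodes, boundary_faces(m, free_only = TRUE),
                       penalty = 1, radius = 0.5)
  expect_equal(rc$n_pairs, 0)
})

test_that("step integrator: equilibrium fixed point, constraint clamps, overdamped decay", {
  m <- make_free_box(1, 1, 1, 0.5)
  st <- sim_state(m)
  st2 <- step_state(st, matrix(0, nrow(m$nodes), 3), dt = 0.1, damping = 1)
  expect_identical(st2$positions, st$positions)
  # bone node under load never moves
  mb <- make_layered_cap(theta_max = 0.08, lateral_spacing = 2.5, seed = 1)
  stb <- sim_state(mb)
  ff <- matrix(1, nrow(mb$nodes), 3)
  stb2 <- step_state(stb, ff, dt = 0.01, damping = 1)
  fixed <- mb$boundary_tags == "bone_fixed"
  expect_identical(stb2$positions[fixed, ], stb$positions[fixed, ])
  expect_false(isTRUE(all.equal(stb2$positions[!fixed, ], stb$positions[!fixed, ])))
  # lateral node velocity has no component along its constraint normal
  lat <- mb$boundary_tags == "lateral"
  resid <- rowSums(stb2$velocities[lat, ] * mb$constraint_n1[lat, ])
  expect_lt(max(abs(resid)), 1e-12)
  # scalar overdamped spring: |x| decays monotonically under the same update
  x <- 1; v <- 0; k <- 1; c <- 10; dt <- 0.1; xs <- x
  for (i in 1:600) {
    v <- (v + dt * (-k * x)) / (1 + c * dt)
    x <- x + dt * v
    xs <- c(xs, x)
  }
  expect_true(all(diff(abs(xs)) <= 1e-12))
  expect_lt(abs(xs[length(xs)]), 1e-2)
})

test_that("zero growth leaves the mesh unmoved to solver tolerance", {
  m <- make_layered_cap(theta_max = 0.08, lateral_spacing = 2.5, seed = 2)
  mat <- species_parameters("sulcata")$material
  r <- simulate(m, mat, growth_spec(0, 0, 0, 0, ramp_steps = 2),
                sim_options(contact_radius = 0, max_steps = 2000))
  expect_lt(max(abs(r$positions - m$nodes)), 1e-6)
})

test_that("free compatible growth relaxes to zero energy with the det-G volume ratio", {
  m <- make_free_box(2, 2, 2, 0.5)
  mat <- material_spec(1, 1, 0.4, 0.4)
  gr <- growth_spec(0.6, 0.3, 0.6, 0.3, ramp_steps = 5)
  r <- simulate(m, mat, gr, sim_options(contact_radius = 0, tol = 1e-5,
                                        max_steps = 20000))
  v0 <- sum(tet_volumes(m))
  m2 <- m; m2$nodes <- r$positions
  expect_equal(sum(tet_volumes(m2)) / v0, 1.6^2 * 1.3, tolerance = 0.01)
  en <- tail(r$diagnostics$elastic_energy, 1)
  expect_lt(en, 1e-8 * mat$mu_dermis * v0)
})

test_that("energy is non-increasing during overdamped relaxation at fixed growth", {
  m <- make_layered_cap(theta_max = 0.08, lateral_spacing = 2.5, seed = 4)
  sp <- species_parameters("graeca")
  arr <- scutefold:::build_sim_arrays(m, sp$material,
                                      growth_spec(0.2, 0, 0.2, 0.1, ramp_steps = 1))
  res <- scutefold:::cpp_relax(m$nodes, m$tets[arr$active, ] - 1L, arr$mu, arr$lam,
                               m$surface_normal[arr$active, ], arr$gt, arr$gn,
                               arr$code, m$constraint_n1, m$constraint_n2,
                               matrix(0L, 0, 3),
                               -1, 5, -1, 0, 10, 1e-5, 4000, 1L, 0L, 5L)
  tr <- res$energy_trace
  expect_gt(length(tr), 10)
  expect_true(all(diff(tr) <= 1e-9 * max(abs(tr))))
})

test_that("simulation trajectories are bit-identical for identical seeds and options", {
  run <- function() {
    m <- make_layered_cap(theta_max = 0.08, lateral_spacing = 2.5, seed = 5)
    sp <- species_parameters("marginata")
    g <- sp$growth; g$ramp_steps <- 5L
    simulate(m, sp$material, g, sim_options(max_steps = 2000, seed = 5))
  }
  a <- run(); b <- run()
  expect_identical(a$positions, b$positions)
  expect_identical(a$diagnostics, b$diagnostics)
})
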