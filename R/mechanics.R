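# ---------------------------------------------------------------------------
# Finite-strain neo-Hookean growth mechanics.
#
# Deformation is decomposed multiplicatively, F = F_e G: the growth tensor G
# is stress-free and the elastic part F_e = F G^-1 carries the compressible
# neo-Hookean energy
#     W = mu/2 (tr(F_e^T F_e) - 3) - mu ln J_e + lam/2 (ln J_e)^2.
# Quasi-statics: damped explicit (semi-implicit Euler) relaxation with
# penalty self-contact, growth ramped linearly to its final value.
# ---------------------------------------------------------------------------

#' Species parameter sets for skin folding simulations
#'
#' Per-layer Young's moduli (relative units -- only the dermis:epidermis ratio
#' matters), Poisson's ratios and final tangential/normal growth fractions
#' for the three tortoise species. Growth is relative to the rigid,
#' non-growing bone layer.
#'
#' @param species one of `"sulcata"`, `"graeca"`, `"marginata"`
#' @return list with elements `material` (class `material_spec`) and
#'   `growth` (class `growth_spec`)
#' @export
species_parameters <- function(species) {
  tab <- list(
    sulcata   = list(E_epid = 3, E_dermis = 1, nu_epid = 0.10, nu_dermis = 0.40,
                     gT_epid = 0.60, gN_epid = 0.0, gT_dermis = 0.6, gN_dermis = 0.3),
    graeca    = list(E_epid = 2, E_dermis = 1, nu_epid = 0.25, nu_dermis = 0.45,
                     gT_epid = 0.50, gN_epid = 0.0, gT_dermis = 0.7, gN_dermis = 0.1),
    marginata = list(E_epid = 2, E_dermis = 1, nu_epid = 0.25, nu_dermis = 0.45,
                     gT_epid = 0.45, gN_epid = 0.0, gT_dermis = 0.7, gN_dermis = 0.1))
  if (!species %in% names(tab))
    stop("unknown species '", species, "'; valid names: ",
         paste(names(tab), collapse = ", "))
  p <- tab[[species]]
  list(material = material_spec(p$E_epid, p$E_dermis, p$nu_epid, p$nu_dermis),
       growth = growth_spec(p$gT_epid, p$gN_epid, p$gT_dermis, p$gN_dermis))
}

#' Per-layer elastic constants
#' @param E_epid,E_dermis Young's moduli (relative units)
#' @param nu_epid,nu_dermis Poisson's ratios in `[0, 0.5)`
#' @return a `material_spec` with derived Lame parameters `mu`, `lam` per layer
#' @export
material_spec <- function(E_epid, E_dermis, nu_epid, nu_dermis) {
  le <- lame_parameters(E_epid, nu_epid)
  ld <- lame_parameters(E_dermis, nu_dermis)
  structure(list(E_epid = E_epid, E_dermis = E_dermis,
                 nu_epid = nu_epid, nu_dermis = nu_dermis,
                 mu_epid = le[["mu"]], lam_epid = le[["lam"]],
                 mu_dermis = ld[["mu"]], lam_dermis = ld[["lam"]]),
            class = "material_spec")
}

#' Per-layer final growth fractions
#' @param gT_epid,gN_epid,gT_dermis,gN_dermis tangential/normal growth; each
#'   must satisfy `1 + g > 0`
#' @param ramp_steps number of linear growth increments for [simulate()]
#' @return a `growth_spec`
#' @export
growth_spec <- function(gT_epid, gN_epid, gT_dermis, gN_dermis,
                        ramp_steps = 50L) {
  g <- c(gT_epid, gN_epid, gT_dermis, gN_dermis)
  if (any(1 + g <= 0)) stop("growth fractions must satisfy 1 + g > 0")
  if (ramp_steps < 1) stop("ramp_steps must be >= 1")
  structure(list(gT_epid = gT_epid, gN_epid = gN_epid,
                 gT_dermis = gT_dermis, gN_dermis = gN_dermis,
                 ramp_steps = as.integer(ramp_steps)),
            class = "growth_spec")
}

#' Lame parameters from Young's modulus and Poisson's ratio
#' @param E Young's modulus, `E > 0`
#' @param nu Poisson's ratio, `0 <= nu < 0.5`
#' @return named vector `c(mu = ..., lam = ...)`
#' @export
lame_parameters <- function(E, nu) {
  if (E <= 0) stop("Young's modulus must be positive")
  if (nu < 0 || nu >= 0.5)
    stop("Poisson's ratio must lie in [0, 0.5); the incompressible limit is unsupported")
  c(mu = E / (2 * (1 + nu)), lam = E * nu / ((1 + nu) * (1 - 2 * nu)))
}

#' Transversely isotropic growth tensor
#'
#' `G = (1 + g_t) (I - n n^T) + (1 + g_n) n n^T`: growth by `g_t` in the plane
#' orthogonal to `normal` and `g_n` along it. `det(G) = (1+g_t)^2 (1+g_n)`.
#'
#' @param normal unit direction of normal growth
#' @param g_t,g_n tangential and normal growth fractions (`1 + g > 0`)
#' @return 3x3 symmetric positive-definite matrix
#' @export
growth_tensor <- function(normal, g_t, g_n) {
  if (abs(sqrt(sum(normal^2)) - 1) > 1e-8) stop("normal must be unit length")
  if (1 + g_t <= 0 || 1 + g_n <= 0) stop("growth must satisfy 1 + g > 0")
  (1 + g_t) * (diag(3) - normal %o% normal) + (1 + g_n) * normal %o% normal
}

#' Neo-Hookean response of one tetrahedral element
#'
#' Computes the element strain energy and exact analytic nodal forces for a
#' tetrahedron under multiplicative growth. The deformation gradient comes
#' from linear shape functions; the energy is integrated over the grown
#' reference volume (`V_ref det G`).
#'
#' @param X_ref 4x3 reference node coordinates (non-degenerate)
#' @param x_cur 4x3 current node coordinates
#' @param G 3x3 growth tensor
#' @param mu,lam Lame parameters
#' @return list with `energy` (scalar) and `forces` (4x3, rows sum to zero)
#' @export
element_response <- function(X_ref, x_cur, G = diag(3), mu = 1, lam = 1) {
  cpp_element_response(X_ref, x_cur, G, mu, lam)
}

#' Simulation options
#'
#' @param dt explicit time step; `NULL` selects the stability bound
#'   `0.5 * h_min * sqrt(rho / (lam + 2 mu))` with unit pseudo-density
#' @param damping viscous drag coefficient; `NULL` targets near-critical
#'   damping of the slowest elastic mode of the domain
#' @param contact_penalty penalty stiffness; `NULL` uses the largest shear
#'   modulus
#' @param contact_radius node-triangle detection radius (0 disables contact)
#' @param contact_rebuild steps between contact candidate rebuilds
#' @param tol relative residual-force convergence tolerance per increment
#' @param max_steps maximum relaxation steps per growth increment
#' @param snapshot_every record node positions every this many increments
#' @param seed integer seed recorded in diagnostics
#' @return a `sim_options` list
#' @export
sim_options <- function(dt = NULL, damping = NULL, contact_penalty = NULL,
                        contact_radius = 0.5, contact_rebuild = 10L,
                        tol = 2e-4, max_steps = 8000L, snapshot_every = 10L,
                        seed = 1L) {
  opt <- list(dt = if (is.null(dt)) -1 else dt,
              damping = if (is.null(damping)) -1 else damping,
              contact_penalty = if (is.null(contact_penalty)) -1 else contact_penalty,
              contact_radius = contact_radius,
              contact_rebuild = as.integer(contact_rebuild),
              tol = tol, max_steps = as.integer(max_steps),
              snapshot_every = as.integer(snapshot_every),
              seed = as.integer(seed))
  stopifnot(opt$tol > 0, opt$max_steps > 0, opt$contact_rebuild > 0)
  structure(opt, class = "sim_options")
}

# map per-tet layer labels to material / growth arrays; bone elements are
# dropped (rigid: all their nodes are clamped)
build_sim_arrays <- function(mesh, material, growth) {
  act <- which(mesh$layer != "bone")
  lay <- mesh$layer[act]
  mu <- ifelse(lay == "epidermis", material$mu_epid, material$mu_dermis)
  lam <- ifelse(lay == "epidermis", material$lam_epid, material$lam_dermis)
  gt <- ifelse(lay == "epidermis", growth$gT_epid, growth$gT_dermis)
  gn <- ifelse(lay == "epidermis", growth$gN_epid, growth$gN_dermis)
  code <- ifelse(mesh$boundary_tags == "bone_fixed", 0L,
                 ifelse(mesh$boundary_tags == "lateral", 2L, 1L))
  list(active = act, mu = mu, lam = lam, gt = gt, gn = gn, code = code)
}

#' Run a growth simulation to quasi-static equilibrium
#'
#' Growth is ramped linearly over `growth$ramp_steps` increments; after each
#' increment the damped system is relaxed until the residual force norm falls
#' below tolerance (or `max_steps` is exhausted, which is recorded as a
#' convergence failure for that increment). Bone is a rigid boundary
#' condition: its nodes never move and bone elements carry no energy.
#'
#' @param mesh a `layered_mesh`
#' @param material a `material_spec`
#' @param growth a `growth_spec`
#' @param options a `sim_options`
#' @return a `sim_result`: final `positions`, per-increment `diagnostics`
#'   data frame (elastic/contact energy, max velocity, min elastic Jacobian,
#'   residual, steps, convergence flag), `snapshots` list, and solver
#'   metadata (`dt`, `damping`, `force_scale`, energy form)
#' @export
simulate <- function(mesh, material, growth, options = sim_options()) {
  validate_mesh(mesh)
  arr <- build_sim_arrays(mesh, material, growth)
  tets <- mesh$tets[arr$active, , drop = FALSE]
  surf <- if (options$contact_radius > 0) {
    boundary_faces(mesh, free_only = TRUE)
  } else matrix(0L, 0, 3)
  res <- cpp_relax(mesh$nodes, tets - 1L, arr$mu, arr$lam,
                   mesh$surface_normal[arr$active, , drop = FALSE],
                   arr$gt, arr$gn, arr$code,
                   mesh$constraint_n1, mesh$constraint_n2,
                   surf - 1L,
                   options$dt, options$damping, options$contact_penalty,
                   options$contact_radius, options$contact_rebuild,
                   options$tol, options$max_steps, growth$ramp_steps,
                   options$snapshot_every, 0L)
  if (nzchar(res$error)) stop("simulation failed: ", res$error)
  diag <- res$diagnostics
  if (any(diag$converged == 0))
    warning("simulation did not converge at ", sum(diag$converged == 0),
            " growth increment(s); partial trajectory returned")
  structure(list(mesh = mesh, material = material, growth = growth,
                 options = options, positions = res$positions,
                 velocities = res$velocities, diagnostics = diag,
                 snapshots = res$snapshots,
                 solver = list(dt = res$dt, damping = res$damping,
                               force_scale = res$force_scale,
                               contact_penalty = res$contact_k,
                               energy_form = "compressible neo-Hookean: W = mu/2 (I1 - 3) - mu ln Je + lam/2 (ln Je)^2",
                               integrator = "semi-implicit Euler, implicit viscous drag")),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  d <- x$diagnostics
  cat("<sim_result>", nrow(x$positions), "nodes,", nrow(d), "growth increments\n")
  cat(sprintf("  final elastic energy %.4g, min J_e %.3f, %s\n",
              d$elastic_energy[nrow(d)], min(d$min_Je),
              if (all(d$converged == 1)) "all increments converged"
              else paste(sum(d$converged == 0), "increments NOT converged")))
  invisible(x)
}

#' Elastic + contact nodal forces for an arbitrary nodal configuration
#'
#' @param mesh a `layered_mesh`
#' @param positions current node positions
#' @param material a `material_spec`
#' @param growth a `growth_spec` (applied at full ramp)
#' @param ramp_fraction growth ramp fraction in `[0, 1]`
#' @return list with `forces` (N x 3), `elastic_energy`, `min_Je`
#' @export
elastic_forces <- function(mesh, positions, material, growth,
                           ramp_fraction = 1) {
  arr <- build_sim_arrays(mesh, material, growth)
  cpp_elastic_forces(mesh$nodes, mesh$tets[arr$active, , drop = FALSE] - 1L,
                     positions, arr$mu, arr$lam,
                     mesh$surface_normal[arr$active, , drop = FALSE],
                     ramp_fraction * arr$gt, ramp_fraction * arr$gn)
}

#' Penalty self-contact forces on the deformed free surface
#'
#' Node-triangle penalty between non-adjacent surface pairs closer than the
#' detection radius; forces are equal and opposite (momentum conserving) and
#' vanish continuously at the detection radius.
#'
#' @param positions current node positions (N x 3)
#' @param surface_tris surface triangles (rows of 1-based vertex indices)
#' @param penalty penalty stiffness
#' @param radius detection radius
#' @return list with `forces` (N x 3), `energy`, `n_pairs`
#' @export
contact_forces <- function(positions, surface_tris, penalty, radius) {
  cpp_contact_forces(positions, surface_tris - 1L, penalty, radius)
}

#' Initialize a simulation state
#' @param mesh a `layered_mesh`
#' @return a `sim_state` with reference positions and zero velocities
#' @export
sim_state <- function(mesh) {
  vol <- tet_volumes(mesh)
  mass <- numeric(nrow(mesh$nodes))
  for (a in 1:4) {
    acc <- tapply(vol / 4, mesh$tets[, a], sum)
    ids <- as.integer(names(acc))
    mass[ids] <- mass[ids] + acc
  }
  structure(list(mesh = mesh, positions = mesh$nodes,
                 velocities = matrix(0, nrow(mesh$nodes), 3),
                 masses = mass, time = 0, ramp_fraction = 0),
            class = "sim_state")
}

#' Advance a simulation state by one damped explicit step
#'
#' Semi-implicit Euler with implicit viscous drag: velocities are updated
#' from the supplied forces, constrained directions projected out
#' (`bone_fixed` nodes clamped, `lateral` nodes confined to their tangent
#' plane), then positions advanced. Identical update rule to the compiled
#' relaxation loop in [simulate()].
#'
#' @param state a `sim_state`
#' @param forces N x 3 nodal forces
#' @param dt time step
#' @param damping viscous drag coefficient
#' @return the advanced `sim_state`
#' @export
step_state <- function(state, forces, dt, damping) {
  mesh <- state$mesh
  v <- (state$velocities + dt * forces / state$masses) / (1 + damping * dt)
  fixed <- mesh$boundary_tags == "bone_fixed"
  v[fixed, ] <- 0
  lat <- mesh$boundary_tags == "lateral"
  if (any(lat)) {
    n1 <- mesh$constraint_n1[lat, , drop = FALSE]
    v[lat, ] <- v[lat, , drop = FALSE] -
      rowSums(v[lat, , drop = FALSE] * n1) * n1
    n2 <- mesh$constraint_n2[lat, , drop = FALSE]
    has2 <- rowSums(n2^2) > 0.5
    if (any(has2)) {
      idx <- which(lat)[has2]
      n2a <- n2[has2, , drop = FALSE]
      v[idx, ] <- v[idx, , drop = FALSE] -
        rowSums(v[idx, , drop = FALSE] * n2a) * n2a
    }
  }
  bad <- !is.finite(v)
  if (any(bad))
    stop("divergent step: non-finite velocities (dt = ", dt, ")")
  state$velocities <- v
  state$positions <- state$positions + dt * v
  state$time <- state$time + dt
  state
}
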