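# ---------------------------------------------------------------------------
# Fold-pattern quantification: discrete mean curvature, crease network
# extraction (thinned concave valleys), polygonal domain segmentation, and
# cross-species pattern statistics.
#
# Sign convention for mean curvature (outward-oriented surfaces):
#   convex bulge (sphere seen from outside)  -> positive
#   concave valley (crease seen from outside) -> negative
#   plane -> 0
# ---------------------------------------------------------------------------

#' Discrete mean curvature of a triangle surface
#'
#' Cotangent-Laplacian mean curvature, area-normalized and signed per the
#' package convention (convex positive, creases negative).
#'
#' @param surface a manifold `tri_surface` with outward-oriented faces
#' @return numeric per-vertex signed mean curvature
#' @export
surface_curvature <- function(surface) {
  bad <- surface_nonmanifold_edges(surface)
  if (nrow(bad))
    stop("surface is non-manifold at ", nrow(bad), " edge(s): ",
         paste(utils::head(apply(bad, 1, paste, collapse = "-"), 5),
               collapse = ", "))
  cpp_mean_curvature(surface$vertices, surface$faces - 1L)
}

# adjacency list of a surface's vertex graph
vertex_adjacency <- function(surface) {
  e <- surface_edges(surface)
  adj <- vector("list", nrow(surface$vertices))
  for (k in seq_len(nrow(e))) {
    adj[[e[k, 1]]] <- c(adj[[e[k, 1]]], e[k, 2])
    adj[[e[k, 2]]] <- c(adj[[e[k, 2]]], e[k, 1])
  }
  adj
}

# topological thinning of a vertex band down to 1-vertex-wide paths.
# Peels band-boundary vertices (those with a neighbor outside the band) in
# order of decreasing curvature (least crease-like first) provided removal
# keeps the local crease neighborhood connected and does not erode
# endpoints (< 2 crease neighbors).
thin_crease_band <- function(in_band, adj, curvature) {
  repeat {
    removed <- FALSE
    cand <- which(in_band)
    cand <- cand[order(curvature[cand], decreasing = TRUE)]
    for (v in cand) {
      nb <- adj[[v]]
      nb_in <- nb[in_band[nb]]
      if (length(nb_in) < 2) next                   # endpoint: protect
      if (!any(!in_band[nb])) next                  # interior of band: wait
      # local connectivity of crease neighbors without v
      sub <- nb_in
      conn <- local_connected(sub, adj, in_band, exclude = v)
      if (!conn) next
      in_band[v] <- FALSE
      removed <- TRUE
    }
    if (!removed) break
  }
  in_band
}

# are the vertices `sub` connected through band vertices within the combined
# 1-ring neighborhoods (excluding `exclude`)?
local_connected <- function(sub, adj, in_band, exclude) {
  if (length(sub) <= 1) return(TRUE)
  region <- unique(c(sub, unlist(adj[sub])))
  region <- region[in_band[region] & region != exclude]
  seen <- sub[1]
  frontier <- sub[1]
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[nxt %in% region & !(nxt %in% seen)]
    seen <- c(seen, nxt)
    frontier <- nxt
    if (all(sub %in% seen)) return(TRUE)
  }
  all(sub %in% seen)
}

#' Extract the crease (fold) network of a deformed surface
#'
#' Vertices whose mean curvature falls below a negative threshold form a
#' crease band, thinned to 1-vertex-wide paths on the surface graph.
#' Components are classified open ("unjoined" edges, with path endpoints) or
#' closed (loops). A `NULL` threshold adapts to the 10th percentile of the
#' curvature distribution; if that percentile is non-negative the surface is
#' judged smooth and the network is empty.
#'
#' @param surface a `tri_surface`
#' @param curvature per-vertex mean curvature (computed if `NULL`)
#' @param threshold negative curvature cutoff, or `NULL` for adaptive
#' @param adaptive_quantile quantile used when `threshold` is `NULL`
#' @return a `fold_network`: `crease_vertices`, `crease_edges`,
#'   `total_crease_length`, `n_components`, `component` membership,
#'   `component_open` logical, `threshold`
#' @export
extract_creases <- function(surface, curvature = NULL, threshold = NULL,
                            adaptive_quantile = 0.10) {
  if (is.null(curvature)) curvature <- surface_curvature(surface)
  adaptive <- is.null(threshold)
  if (adaptive) threshold <- unname(quantile(curvature, adaptive_quantile))
  empty <- function() structure(
    list(crease_vertices = integer(0), crease_edges = matrix(0L, 0, 2),
         total_crease_length = 0, n_components = 0L,
         component = integer(0), component_open = logical(0),
         threshold = threshold, adaptive = adaptive),
    class = "fold_network")
  if (threshold >= 0) {
    if (!adaptive) stop("crease threshold must be negative (creases are concave)")
    return(empty())
  }
  in_band <- curvature < threshold
  if (!any(in_band)) return(empty())
  adj <- vertex_adjacency(surface)
  in_band <- thin_crease_band(in_band, adj, curvature)
  cv <- which(in_band)
  e <- surface_edges(surface)
  ce <- e[in_band[e[, 1]] & in_band[e[, 2]], , drop = FALSE]
  len <- if (nrow(ce)) {
    sum(sqrt(rowSums((surface$vertices[ce[, 1], , drop = FALSE] -
                      surface$vertices[ce[, 2], , drop = FALSE])^2)))
  } else 0
  # components over the crease subgraph (isolated crease vertices included)
  g <- igraph::make_empty_graph(n = length(cv), directed = FALSE)
  remap <- integer(nrow(surface$vertices))
  remap[cv] <- seq_along(cv)
  if (nrow(ce))
    g <- igraph::add_edges(g, t(matrix(remap[ce], ncol = 2)))
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  open_flags <- vapply(seq_len(comp$no), function(ci) {
    any(deg[comp$membership == ci] <= 1)
  }, logical(1))
  structure(list(crease_vertices = cv, crease_edges = ce,
                 total_crease_length = len, n_components = comp$no,
                 component = comp$membership, component_open = open_flags,
                 threshold = threshold, adaptive = adaptive),
            class = "fold_network")
}

#' @export
print.fold_network <- function(x, ...) {
  cat("<fold_network>", length(x$crease_vertices), "crease vertices,",
      x$n_components, "components (", sum(x$component_open), "open ),",
      "total length", signif(x$total_crease_length, 4), "\n")
  invisible(x)
}

#' Segment the surface into polygonal domains bounded by creases
#'
#' Flood-fills non-crease vertices into connected domains; domains touching
#' the surface boundary are flagged.
#'
#' @param surface a `tri_surface`
#' @param network a `fold_network` extracted from this surface
#' @return list: `labels` (per-vertex domain id, `NA` on creases), `areas`
#'   (per-domain vertex-area sums), `touches_boundary` logical per domain
#' @export
segment_domains <- function(surface, network) {
  nv <- nrow(surface$vertices)
  crease <- rep(FALSE, nv)
  crease[network$crease_vertices] <- TRUE
  e <- surface_edges(surface)
  keep <- !crease[e[, 1]] & !crease[e[, 2]]
  g <- igraph::make_empty_graph(n = nv, directed = FALSE)
  if (any(keep))
    g <- igraph::add_edges(g, t(e[keep, , drop = FALSE]))
  comp <- igraph::components(g)
  labels <- comp$membership
  labels[crease] <- NA
  # relabel only non-crease components compactly
  present <- sort(unique(labels[!is.na(labels)]))
  labels <- match(labels, present)
  nd <- length(present)
  va <- vertex_areas(surface)
  areas <- vapply(seq_len(nd), function(d) sum(va[which(labels == d)]), 0)
  bv <- surface_boundary_vertices(surface)
  touches <- vapply(seq_len(nd), function(d) any(bv %in% which(labels == d)),
                    logical(1))
  list(labels = labels, areas = areas, touches_boundary = touches)
}

#' Dominant pattern wavelength by spectral analysis of surface height
#'
#' Vertices are projected onto their PCA plane; heights (third principal
#' component) are binned on a regular grid and the radially averaged 2D power
#' spectrum's peak gives the dominant wavelength. Wavelengths longer than
#' half the domain (including the overall dome shape) are excluded.
#'
#' @param surface a `tri_surface`
#' @param nbins grid resolution (`NULL` = from vertex density)
#' @return wavelength in surface length units, or `NA` if the surface is too
#'   small for a spectral estimate
#' @export
dominant_wavelength <- function(surface, nbins = NULL) {
  v <- surface$vertices
  if (nrow(v) < 64) {
    message("surface too small for a spectral estimate")
    return(NA_real_)
  }
  ctr <- colMeans(v)
  vc <- sweep(v, 2, ctr)
  ev <- eigen(crossprod(vc) / nrow(vc), symmetric = TRUE)
  u <- vc %*% ev$vectors[, 1]
  w <- vc %*% ev$vectors[, 2]
  h <- vc %*% ev$vectors[, 3]
  if (is.null(nbins)) nbins <- max(16L, floor(sqrt(nrow(v) / 2)))
  Lu <- diff(range(u)); Lw <- diff(range(w))
  bu <- pmin(nbins, pmax(1, ceiling((u - min(u)) / Lu * nbins)))
  bw <- pmin(nbins, pmax(1, ceiling((w - min(w)) / Lw * nbins)))
  grid <- matrix(0, nbins, nbins)
  cnt <- matrix(0, nbins, nbins)
  for (i in seq_along(h)) {
    grid[bu[i], bw[i]] <- grid[bu[i], bw[i]] + h[i]
    cnt[bu[i], bw[i]] <- cnt[bu[i], bw[i]] + 1
  }
  filled <- cnt > 0
  grid[filled] <- grid[filled] / cnt[filled]
  grid[!filled] <- mean(grid[filled])
  grid <- grid - mean(grid)
  P <- Mod(fft(grid))^2
  ku <- c(0:(nbins %/% 2), -((nbins - nbins %/% 2 - 1):1)) / Lu
  kw <- c(0:(nbins %/% 2), -((nbins - nbins %/% 2 - 1):1)) / Lw
  kmag <- sqrt(outer(ku^2, kw^2, "+"))
  kmin <- 2 / max(Lu, Lw)            # exclude DC and > half-domain wavelengths
  sel <- kmag >= kmin
  if (!any(sel)) {
    message("surface too small for a spectral estimate")
    return(NA_real_)
  }
  # radial average in log-spaced wavenumber bands, then peak
  kv <- kmag[sel]; pv <- P[sel]
  br <- exp(seq(log(min(kv)), log(max(kv)), length.out = 40))
  band <- cut(kv, breaks = br, include.lowest = TRUE)
  pm <- tapply(pv, band, mean)
  km <- tapply(kv, band, mean)
  pk <- which.max(pm)
  1 / unname(km[pk])
}

#' Summary statistics of a folded surface pattern
#'
#' @param surface a `tri_surface`
#' @param network a `fold_network` (computed adaptively if `NULL`)
#' @param domains output of [segment_domains()] (computed if `NULL`)
#' @return a `pattern_stats` list: `n_domains`, `mean_domain_area`,
#'   `crease_length_density` (length per unit area),
#'   `fraction_open_creases`, `dominant_wavelength`, `total_area`
#' @export
pattern_statistics <- function(surface, network = NULL, domains = NULL) {
  if (is.null(network)) network <- extract_creases(surface)
  if (is.null(domains)) domains <- segment_domains(surface, network)
  A <- surface_area(surface)
  nd <- length(domains$areas)
  structure(list(
    n_domains = nd,
    mean_domain_area = if (nd) mean(domains$areas) else NA_real_,
    crease_length_density = network$total_crease_length / A,
    fraction_open_creases = if (network$n_components)
      mean(network$component_open) else 0,
    dominant_wavelength = dominant_wavelength(surface),
    total_area = A,
    threshold = network$threshold),
    class = "pattern_stats")
}

#' @export
print.pattern_stats <- function(x, ...) {
  cat("<pattern_stats>\n")
  cat(sprintf("  domains: %d (mean area %.3g)\n", x$n_domains, x$mean_domain_area))
  cat(sprintf("  crease length density: %.4g per unit area\n",
              x$crease_length_density))
  cat(sprintf("  open crease fraction: %.2f\n", x$fraction_open_creases))
  cat(sprintf("  dominant wavelength: %.3g\n", x$dominant_wavelength))
  invisible(x)
}

#' Rank species by fold intensity across seeds
#'
#' Orders species by median crease length density over replicate simulations
#' (different jitter seeds) and attaches a seed-resampling (bootstrap)
#' confidence for the observed strict ordering. Requires at least three
#' seeds per species; ties yield no ordering claim.
#'
#' @param stats data frame with columns `species`, `seed`,
#'   `crease_length_density`
#' @param expected optional character vector giving the hypothesized order,
#'   most folded first
#' @param n_boot bootstrap resamples
#' @return list: `ranking` (most folded first), `medians`, `confidence`
#'   (bootstrap fraction reproducing the ranking), `tie`, and
#'   `matches_expected` when `expected` is given
#' @export
compare_species <- function(stats,
                            expected = c("sulcata", "graeca", "marginata"),
                            n_boot = 500) {
  stopifnot(is.data.frame(stats),
            all(c("species", "seed", "crease_length_density") %in% names(stats)))
  sp <- split(stats$crease_length_density, stats$species)
  if (length(sp) < 2) stop("need at least two labeled species")
  ns <- vapply(sp, length, 0L)
  if (any(ns < 3))
    stop("refusing to rank: fewer than 3 seeds for ",
         paste(names(ns)[ns < 3], collapse = ", "),
         " (variance unestimable)")
  med <- vapply(sp, median, 0)
  ord <- order(med, decreasing = TRUE)
  ranking <- names(med)[ord]
  tie <- any(diff(sort(med, decreasing = TRUE)) == 0)
  boot_match <- local_seed(1L, {
    hits <- 0L
    for (b in seq_len(n_boot)) {
      bm <- vapply(sp, function(x) median(sample(x, length(x), replace = TRUE)), 0)
      if (!any(duplicated(bm)) &&
          identical(names(bm)[order(bm, decreasing = TRUE)], ranking))
        hits <- hits + 1L
    }
    hits / n_boot
  })
  out <- list(ranking = ranking, medians = med[ord],
              confidence = boot_match, tie = tie)
  if (!is.null(expected) && all(expected %in% names(med))) {
    out$matches_expected <- !tie &&
      identical(ranking[ranking %in% expected], expected)
  }
  out
}

#' Simulate and quantify fold patterns for several species
#'
#' End-to-end survey: for each species and seed, generates the default dome
#' (jitter seeded), runs the growth simulation, and measures the crease
#' network. Cross-specimen comparability requires one common crease
#' threshold: it is fixed at the pooled `threshold_quantile` of the curvature
#' distributions of all surveyed surfaces.
#'
#' @param species character vector of species names
#' @param seeds integer vector of jitter seeds (>= 3 for [compare_species()])
#' @param mesh_args list of [make_layered_cap()] overrides
#' @param options a `sim_options`
#' @param growth_scale multiplier applied to all growth fractions (1 = the
#'   species parameter-table values)
#' @param threshold_quantile pooled curvature quantile fixing the common
#'   crease threshold
#' @return list: `stats` data frame (`species`, `seed`,
#'   `crease_length_density`, `n_components`, `fraction_open`, `n_domains`,
#'   `area_ratio`), `threshold`, `surfaces` (named list of `tri_surface`)
#' @export
species_fold_survey <- function(species = c("sulcata", "graeca", "marginata"),
                                seeds = 1:3, mesh_args = list(),
                                options = sim_options(),
                                growth_scale = 1,
                                threshold_quantile = 0.10) {
  runs <- list()
  for (sp in species) for (sd in seeds) {
    pars <- species_parameters(sp)
    if (growth_scale != 1) {
      g <- pars$growth
      pars$growth <- growth_spec(growth_scale * g$gT_epid,
                                 growth_scale * g$gN_epid,
                                 growth_scale * g$gT_dermis,
                                 growth_scale * g$gN_dermis, g$ramp_steps)
    }
    mesh <- do.call(make_layered_cap, c(mesh_args, list(seed = sd)))
    opt <- options
    opt$seed <- as.integer(sd)
    sim <- simulate(mesh, pars$material, pars$growth, opt)
    surf <- free_surface(mesh, sim$positions)
    surf0 <- free_surface(mesh, mesh$nodes)
    runs[[paste(sp, sd, sep = "_")]] <-
      list(species = sp, seed = sd, surf = surf,
           curvature = surface_curvature(surf),
           area_ratio = surface_area(surf) / surface_area(surf0))
  }
  thr <- unname(quantile(unlist(lapply(runs, `[[`, "curvature")),
                         threshold_quantile))
  stats <- do.call(rbind, lapply(runs, function(r) {
    net <- extract_creases(r$surf, r$curvature, threshold = thr)
    st <- pattern_statistics(r$surf, net)
    data.frame(species = r$species, seed = r$seed,
               crease_length_density = st$crease_length_density,
               n_components = net$n_components,
               fraction_open = st$fraction_open_creases,
               n_domains = st$n_domains, area_ratio = r$area_ratio)
  }))
  rownames(stats) <- NULL
  list(stats = stats, threshold = thr,
       surfaces = lapply(runs, `[[`, "surf"))
}
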