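# ---------------------------------------------------------------------------
# Hertzian spherical-contact analysis of load-displacement curves.
#
# Model: F = (4/3) E_eff sqrt(R) delta^(3/2), with F in uN, delta and R in
# um, E_eff in Pa (the 1e-6 factor below converts Pa um^2 to uN). E_eff is
# the instrument-style effective modulus, with no (1 - nu^2) correction; to
# convert to a true modulus divide by (1 - nu^2).
# ---------------------------------------------------------------------------

#' Hertz spherical-contact force
#'
#' @param delta indentation depth (um), `0 <= delta << R`
#' @param E_eff effective Young's modulus (Pa)
#' @param R probe tip radius (um)
#' @return force in uN
#' @export
hertz_force <- function(delta, E_eff, R = 99) {
  if (any(delta < 0)) stop("indentation depth must be nonnegative")
  (4 / 3) * E_eff * sqrt(R) * delta^1.5 * 1e-6
}

#' Generate synthetic indentation curves
#'
#' Each curve is the Hertz forward model on a uniform depth grid plus seeded
#' multiplicative Gaussian noise (standard deviation `noise_sd` as a fraction
#' of the local force, hence of the max force at terminal depth). The true
#' modulus is recorded in every curve.
#'
#' @param E_true true effective modulus (Pa)
#' @param probe_radius tip radius (um)
#' @param max_depth terminal depth (um); must stay in the Hertz small-contact
#'   regime (`< probe_radius / 10`)
#' @param n_curves number of replicate curves
#' @param noise_sd noise fraction
#' @param seed integer seed
#' @param n_points samples per curve
#' @return list of `indentation_curve` objects
#' @export
make_indentation_curves <- function(E_true, probe_radius = 99, max_depth = 2,
                                    n_curves = 1, noise_sd = 0, seed = 1L,
                                    n_points = 100) {
  stopifnot(E_true > 0, noise_sd >= 0, n_points >= 10)
  if (max_depth >= probe_radius / 10)
    stop("max_depth >= probe_radius/10 violates the Hertz small-contact regime")
  delta <- seq(0, max_depth, length.out = n_points)
  f0 <- hertz_force(delta, E_true, probe_radius)
  local_seed(seed, {
    lapply(seq_len(n_curves), function(i) {
      f <- if (noise_sd > 0) f0 * (1 + rnorm(n_points, 0, noise_sd)) else f0
      structure(list(displacement = delta, force = f,
                     probe_radius = probe_radius, truth_modulus = E_true,
                     curve_id = i),
                class = "indentation_curve")
    })
  })
}

#' Fit the Hertz model to a load-displacement curve
#'
#' Least squares in the linearized model `F = k delta^(3/2)` (linear in the
#' modulus after the 3/2-power transform); `E_eff = 3 k / (4 sqrt(R))`.
#' Fit quality is the coefficient of determination of the fitted curve
#' against the data (clamped at 0). Optionally a contact-point offset
#' `delta_0` (and force baseline) is pre-estimated by a 1D search.
#'
#' @param curve an `indentation_curve` with >= 10 monotone samples
#' @param estimate_offset estimate a zero-depth contact offset before fitting
#' @param curve_id,replicate_id,grid_position identifiers carried through
#' @return an `indentation_result`: `E_eff` (Pa, `NA` on fit failure),
#'   `fit_quality` in `[0, 1]`, identifiers
#' @export
fit_hertz <- function(curve, estimate_offset = FALSE,
                      curve_id = curve$curve_id, replicate_id = 1L,
                      grid_position = NA_integer_) {
  d <- curve$displacement
  f <- curve$force
  if (length(d) < 10) stop("need at least 10 samples")
  if (any(diff(d) <= 0)) stop("displacement must be strictly increasing")
  R <- curve$probe_radius
  fit_at <- function(d0) {
    dd <- pmax(d - d0, 0)
    x <- dd^1.5
    k <- sum(f * x) / sum(x^2)
    ss_res <- sum((f - k * x)^2)
    list(k = k, ss_res = ss_res)
  }
  d0 <- 0
  if (estimate_offset) {
    cand <- seq(0, 0.25 * max(d), length.out = 26)
    sse <- vapply(cand, function(z) fit_at(z)$ss_res, 0)
    d0 <- cand[which.min(sse)]
  }
  ft <- fit_at(d0)
  ss_tot <- sum((f - mean(f))^2)
  r2 <- if (ss_tot > 0) 1 - ft$ss_res / ss_tot else as.numeric(ft$ss_res == 0)
  quality <- max(0, min(1, r2))
  E <- 3 * ft$k / (4 * sqrt(R)) * 1e6
  ok <- is.finite(E) && E > 0
  structure(list(E_eff = if (ok) E else NA_real_,
                 fit_quality = if (ok) quality else 0,
                 contact_offset = d0,
                 curve_id = curve_id, replicate_id = replicate_id,
                 grid_position = grid_position),
            class = "indentation_result")
}

#' @export
print.indentation_result <- function(x, ...) {
  cat(sprintf("<indentation_result> E_eff = %s Pa, R^2 = %.4f\n",
              format(x$E_eff, digits = 5), x$fit_quality))
  invisible(x)
}

#' Collect indentation results into a data frame
#' @param results list of `indentation_result`
#' @return data frame with one row per result
#' @export
indentation_results_df <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(replicate_id = r$replicate_id, curve_id = r$curve_id,
               grid_position = r$grid_position, E_eff = r$E_eff,
               fit_quality = r$fit_quality)
  }))
}

#' Filter by fit quality and aggregate per replicate
#'
#' Drops fits with quality below `min_quality` (inclusive threshold: quality
#' exactly at the cutoff is retained) and reports mean, SD and retention
#' count of the effective modulus per biological replicate, mirroring the
#' grid indentation protocol (30 curves in a 3 x 10 grid, or 9 in 3 x 3).
#'
#' @param results list of `indentation_result` or a data frame from
#'   [indentation_results_df()]
#' @param min_quality retention threshold on fit quality
#' @param grid integer pair `(rows, cols)`; each replicate must contribute
#'   exactly `prod(grid)` results
#' @return data frame: `replicate_id`, `mean_E`, `sd_E`, `n_retained`,
#'   `missing` (no curve survived)
#' @export
filter_and_aggregate <- function(results, min_quality = 0.95, grid = c(3, 10)) {
  df <- if (is.data.frame(results)) results else indentation_results_df(results)
  expected <- prod(grid)
  out <- lapply(split(df, df$replicate_id), function(g) {
    if (nrow(g) != expected)
      stop("replicate ", g$replicate_id[1], " has ", nrow(g),
           " results but the grid is ", grid[1], " x ", grid[2])
    keep <- g[!is.na(g$E_eff) & g$fit_quality >= min_quality, ]
    if (!nrow(keep)) {
      data.frame(replicate_id = g$replicate_id[1], mean_E = NA_real_,
                 sd_E = NA_real_, n_retained = 0L, missing = TRUE)
    } else {
      data.frame(replicate_id = g$replicate_id[1], mean_E = mean(keep$E_eff),
                 sd_E = if (nrow(keep) > 1) sd(keep$E_eff) else 0,
                 n_retained = nrow(keep), missing = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Plot a developmental series of replicate-mean moduli
#'
#' Mean +/- SD per biological replicate grouped by stage label: the standard
#' presentation of a stiffness developmental series.
#'
#' @param summaries data frame from [filter_and_aggregate()] plus a `stage`
#'   column
#' @param ... passed to [graphics::plot()]
#' @return invisibly, the plotted data frame
#' @export
plot_modulus_series <- function(summaries, ...) {
  stopifnot("stage" %in% names(summaries))
  s <- summaries[!summaries$missing, ]
  xs <- as.numeric(factor(s$stage))
  graphics::plot(xs + runif(nrow(s), -0.1, 0.1), s$mean_E,
                 xaxt = "n", xlab = "stage", ylab = "effective modulus (Pa)",
                 pch = 19, ...)
  graphics::axis(1, at = sort(unique(xs)), labels = levels(factor(s$stage)))
  graphics::arrows(xs, s$mean_E - s$sd_E, xs, s$mean_E + s$sd_E,
                   angle = 90, code = 3, length = 0.04)
  invisible(s)
}
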