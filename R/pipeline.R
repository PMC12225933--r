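# ---------------------------------------------------------------------------
# Pipeline glue: flat-text run configuration (keys mirror the species
# parameter-table symbols so configs diff cleanly against it), derived
# per-stage seeds, and a manifest-writing runner.
# ---------------------------------------------------------------------------

CONFIG_KEYS <- list(
  # global
  stages = "character", seed = "integer", log_level = "character",
  species = "character",
  # material / growth (parameter-table symbol names)
  E_epid = "numeric", E_dermis = "numeric", nu_epid = "numeric",
  nu_dermis = "numeric", gT_epid = "numeric", gN_epid = "numeric",
  gT_dermis = "numeric", gN_dermis = "numeric", ramp_steps = "integer",
  # mesh
  cap_radius = "numeric", h_epid = "numeric", h_dermis = "numeric",
  h_bone = "numeric", theta_max = "numeric", resolution = "integer",
  lateral_spacing = "numeric", perturb_amplitude = "numeric",
  # solver
  tol = "numeric", max_steps = "integer", contact_radius = "numeric",
  snapshot_every = "integer",
  # phantom
  phantom_nx = "integer", phantom_ny = "integer", phantom_nz = "integer",
  phantom_h_epid = "numeric", phantom_h_dermis = "numeric",
  n_cells = "integer", noise_sd = "numeric",
  # indentation
  E_true = "numeric", probe_radius = "numeric", max_depth = "numeric",
  n_curves = "integer", indent_noise_sd = "numeric",
  grid_rows = "integer", grid_cols = "integer", min_quality = "numeric")

#' Build a validated run configuration
#'
#' Unknown keys are rejected by name. Defaults: a sulcata cap simulation with
#' pattern analysis.
#' @param ... configuration entries (see the package vignette for the key
#'   list)
#' @return a `run_config` list
#' @export
run_config <- function(...) {
  cfg <- list(...)
  bad <- setdiff(names(cfg), names(CONFIG_KEYS))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  defaults <- list(stages = c("generate-mesh", "simulate", "analyze-pattern"),
                   seed = 1L, log_level = "info", species = "sulcata",
                   ramp_steps = 50L, resolution = 2L,
                   lateral_spacing = 1.6, tol = 2e-4, max_steps = 8000L,
                   contact_radius = 0.5, snapshot_every = 10L,
                   perturb_amplitude = 0.05)
  cfg <- utils::modifyList(defaults, cfg)
  structure(cfg, class = "run_config")
}

#' Write a run configuration as flat `key = value` text
#' @param config a `run_config`
#' @param path output file
#' @return the path, invisibly
#' @export
write_run_config <- function(config, path) {
  ks <- sort(names(config))
  lines <- vapply(ks, function(k) {
    v <- config[[k]]
    txt <- if (is.character(v)) v else sprintf("%.17g", v)
    sprintf("%s = %s", k, paste(txt, collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat `key = value` run configuration
#' @param path config file
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !grepl("^\\s*#", ln)]
  kv <- strsplit(ln, "\\s*=\\s*")
  cfg <- list()
  for (p in kv) {
    k <- trimws(p[1])
    if (!k %in% names(CONFIG_KEYS)) stop("unknown config key: ", k)
    raw <- strsplit(trimws(p[2]), ",")[[1]]
    typ <- CONFIG_KEYS[[k]]
    cfg[[k]] <- switch(typ,
                       character = raw,
                       integer = as.integer(raw),
                       numeric = as.numeric(raw))
  }
  do.call(run_config, cfg)
}

# deterministic per-stage seed derivation (documented rule)
stage_seed <- function(global_seed, stage_index) {
  as.integer((as.double(global_seed) * 1009 + 9176 * stage_index) %% 2147483647)
}

# FNV-1a hash over the canonical serialized config (hex string)
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), b) + 2^30  # keep in int range
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

log_msg <- function(level, config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s", level, paste0(...)))
}

#' Run a configured analysis pipeline
#'
#' Executes the requested stages in order, writing every artifact plus a
#' `manifest.json` recording the config, its hash, derived per-stage seeds
#' and per-stage output files. Rerunning with the same config and seed
#' reproduces byte-identical outputs (the manifest's `timestamp` field
#' excepted). On a stage failure the manifest records the failure point and
#' downstream stages are skipped.
#'
#' Stages: `generate-mesh`, `simulate`, `analyze-pattern`,
#' `generate-phantom`, `segment`, `generate-curves`, `fit-indentation`.
#'
#' @param config a `run_config`
#' @param out_dir output directory (created)
#' @return the manifest list, invisibly; also written as JSON
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config),
                   config_hash = fnv1a_hash(unclass(config)),
                   global_seed = config$seed,
                   seed_rule = "stage_seed = (seed * 1009 + 9176 * stage_index) mod 2147483647",
                   package_version = as.character(utils::packageVersion("scutefold")),
                   stages = list(), status = "ok")
  env <- new.env()
  stage_fns <- list(
    "generate-mesh" = function(sd) {
      args <- intersect(names(config),
                        c("cap_radius", "h_epid", "h_dermis", "h_bone",
                          "theta_max", "resolution", "lateral_spacing",
                          "perturb_amplitude"))
      env$mesh <- do.call(make_layered_cap, c(config[args], list(seed = sd)))
      p <- file.path(out_dir, "mesh.vtk")
      write_vtk_mesh(env$mesh, p)
      "mesh.vtk"
    },
    "simulate" = function(sd) {
      if (is.null(env$mesh)) env$mesh <- read_vtk_mesh(file.path(out_dir, "mesh.vtk"))
      pars <- if (!is.null(config$species) &&
                  !all(c("E_epid", "gT_epid") %in% names(config))) {
        species_parameters(config$species)
      } else {
        list(material = material_spec(config$E_epid, config$E_dermis,
                                      config$nu_epid, config$nu_dermis),
             growth = growth_spec(config$gT_epid, config$gN_epid,
                                  config$gT_dermis, config$gN_dermis,
                                  config$ramp_steps))
      }
      pars$growth$ramp_steps <- as.integer(config$ramp_steps)
      opt <- sim_options(contact_radius = config$contact_radius,
                         tol = config$tol, max_steps = config$max_steps,
                         snapshot_every = config$snapshot_every, seed = sd)
      env$sim <- simulate(env$mesh, pars$material, pars$growth, opt)
      files <- character(0)
      for (k in seq_along(env$sim$snapshots)) {
        fn <- sprintf("trajectory_%03d.vtk", k)
        write_vtk_mesh(env$mesh, file.path(out_dir, fn),
                       positions = env$sim$snapshots[[k]])
        files <- c(files, fn)
      }
      write.csv(env$sim$diagnostics, file.path(out_dir, "diagnostics.csv"),
                row.names = FALSE)
      c(files, "diagnostics.csv")
    },
    "analyze-pattern" = function(sd) {
      surf <- free_surface(env$mesh, env$sim$positions)
      cur <- surface_curvature(surf)
      net <- extract_creases(surf, cur)
      stats <- pattern_statistics(surf, net)
      surf$scalars$mean_curvature <- cur
      write_ply_surface(surf, file.path(out_dir, "surface_final.ply"))
      write_fold_network_csv(surf, net, file.path(out_dir, "fold_network.csv"))
      jsonlite::write_json(unclass(stats), file.path(out_dir, "pattern_stats.json"),
                           auto_unbox = TRUE, digits = NA)
      c("surface_final.ply", "fold_network.csv", "pattern_stats.json")
    },
    "generate-phantom" = function(sd) {
      shape <- c(config$phantom_nx %||% 64L, config$phantom_ny %||% 64L,
                 config$phantom_nz %||% 48L)
      env$phantom <- make_image_phantom(
        shape = shape, h_epid = config$phantom_h_epid %||% 4,
        h_dermis = config$phantom_h_dermis %||% 12,
        n_cells = config$n_cells %||% 0L,
        noise_sd = config$noise_sd %||% 0, seed = sd)
      write_phantom_tiff(env$phantom, file.path(out_dir, "phantom.tif"))
      c("phantom.tif", "phantom.tif.json")
    },
    "segment" = function(sd) {
      seg <- segment_skin_surfaces(env$phantom$stack)
      th <- thickness_map(seg$outer, seg$inner)
      seg$outer$scalars$thickness <- th
      write_ply_surface(seg$outer, file.path(out_dir, "surface_outer.ply"))
      write_ply_surface(seg$inner, file.path(out_dir, "surface_inner.ply"))
      cells <- detect_cells(env$phantom$cell_stack)
      write.csv(data.frame(x = cells$centroids[, 1], y = cells$centroids[, 2],
                           z = cells$centroids[, 3], score = cells$scores),
                file.path(out_dir, "cells.csv"), row.names = FALSE)
      dens <- proliferation_density(cells, phantom_layer_masks(env$phantom))
      write.csv(dens, file.path(out_dir, "density.csv"), row.names = FALSE)
      c("surface_outer.ply", "surface_inner.ply", "cells.csv", "density.csv")
    },
    "generate-curves" = function(sd) {
      env$curves <- make_indentation_curves(
        E_true = config$E_true %||% 1e5,
        probe_radius = config$probe_radius %||% 99,
        max_depth = config$max_depth %||% 2,
        n_curves = config$n_curves %||% 30L,
        noise_sd = config$indent_noise_sd %||% 0.01, seed = sd)
      write_indentation_csv(env$curves, file.path(out_dir, "curves"))
      file.path("curves", c(sprintf("curve_%03d.csv", seq_along(env$curves)),
                            "probe.json"))
    },
    "fit-indentation" = function(sd) {
      if (is.null(env$curves))
        env$curves <- read_indentation_csv(file.path(out_dir, "curves"))
      grid <- c(config$grid_rows %||% 3L,
                config$grid_cols %||% (length(env$curves) %/% (config$grid_rows %||% 3L)))
      res <- lapply(seq_along(env$curves), function(i) {
        fit_hertz(env$curves[[i]], curve_id = i, replicate_id = 1L,
                  grid_position = i)
      })
      df <- indentation_results_df(res)
      write.csv(df, file.path(out_dir, "indentation_results.csv"),
                row.names = FALSE)
      summ <- filter_and_aggregate(df, config$min_quality %||% 0.95, grid)
      write.csv(summ, file.path(out_dir, "indentation_summary.csv"),
                row.names = FALSE)
      c("indentation_results.csv", "indentation_summary.csv")
    })
  for (i in seq_along(config$stages)) {
    st <- config$stages[i]
    if (!st %in% names(stage_fns)) stop("unknown stage: ", st)
    sd <- stage_seed(config$seed, i)
    log_msg("info", config, "stage ", st, " (seed ", sd, ")")
    res <- tryCatch(list(files = stage_fns[[st]](sd), error = NULL),
                    error = function(e) list(files = character(0),
                                             error = conditionMessage(e)))
    manifest$stages[[st]] <- list(index = i, seed = sd, files = res$files,
                                  error = res$error)
    if (!is.null(res$error)) {
      manifest$status <- paste0("failed at stage ", st)
      log_msg("error", config, "stage ", st, " failed: ", res$error)
      break
    }
  }
  manifest$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
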