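# ---------------------------------------------------------------------------
# File I/O: legacy ASCII VTK unstructured grids (tet meshes, trajectories),
# ASCII PLY (triangle surfaces), multi-page TIFF + JSON sidecar (phantoms),
# CSV + JSON (indentation curves).
#
# Integer data array keys:
#   layer:        1 = epidermis, 2 = dermis, 3 = bone        (cell data)
#   boundary_tag: 0 = bone_fixed, 1 = free, 2 = lateral      (point data)
# ---------------------------------------------------------------------------

LAYER_CODES <- c(epidermis = 1L, dermis = 2L, bone = 3L)
TAG_CODES <- c(bone_fixed = 0L, free = 1L, lateral = 2L)

fmt_num <- function(x) sprintf("%.9g", x)

#' Write a layered mesh (or deformed state) as legacy ASCII VTK
#'
#' @param mesh a `layered_mesh`
#' @param path output file
#' @param positions node positions to write (defaults to reference)
#' @return the path, invisibly
#' @export
write_vtk_mesh <- function(mesh, path, positions = mesh$nodes) {
  n <- nrow(positions); m <- nrow(mesh$tets)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "layered tetrahedral mesh (layer: 1=epidermis 2=dermis 3=bone; boundary_tag: 0=bone_fixed 1=free 2=lateral)",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(apply(positions, 1, function(p) paste(fmt_num(p), collapse = " ")),
             con)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  writeLines(paste(4, mesh$tets[, 1] - 1, mesh$tets[, 2] - 1,
                   mesh$tets[, 3] - 1, mesh$tets[, 4] - 1), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  writeLines(c(sprintf("CELL_DATA %d", m),
               "SCALARS layer int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(LAYER_CODES[mesh$layer]), con)
  writeLines(c("NORMALS surface_normal double"), con)
  writeLines(apply(mesh$surface_normal, 1,
                   function(p) paste(fmt_num(p), collapse = " ")), con)
  writeLines(c(sprintf("POINT_DATA %d", n),
               "SCALARS boundary_tag int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(TAG_CODES[mesh$boundary_tags]), con)
  invisible(path)
}

#' Read a layered mesh written by [write_vtk_mesh()]
#' @param path VTK file
#' @return a `layered_mesh`
#' @export
read_vtk_mesh <- function(path) {
  ln <- trimws(readLines(path))
  ip <- grep("^POINTS", ln)[1]
  n <- as.integer(strsplit(ln[ip], " +")[[1]][2])
  pts <- matrix(as.numeric(unlist(strsplit(ln[(ip + 1):(ip + n)], " +"))),
                ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", ln)[1]
  m <- as.integer(strsplit(ln[ic], " +")[[1]][2])
  cells <- matrix(as.integer(unlist(strsplit(ln[(ic + 1):(ic + m)], " +"))),
                  ncol = 5, byrow = TRUE)
  tets <- cells[, 2:5, drop = FALSE] + 1L
  il <- grep("^SCALARS layer", ln)[1]
  layer_codes <- as.integer(ln[(il + 2):(il + 1 + m)])
  layer <- names(LAYER_CODES)[layer_codes]
  innm <- grep("^NORMALS surface_normal", ln)[1]
  nrm <- matrix(as.numeric(unlist(strsplit(ln[(innm + 1):(innm + m)], " +"))),
                ncol = 3, byrow = TRUE)
  it <- grep("^SCALARS boundary_tag", ln)[1]
  tag_codes <- as.integer(ln[(it + 2):(it + 1 + n)])
  tags <- names(TAG_CODES)[tag_codes + 1L]
  mesh <- new_layered_mesh(pts, tets, layer, nrm, tags)
  validate_mesh(mesh)
}

#' Write a triangle surface as ASCII PLY
#'
#' Per-vertex scalar slots are written as extra float properties.
#' @param surface a `tri_surface`
#' @param path output file
#' @return the path, invisibly
#' @export
write_ply_surface <- function(surface, path) {
  v <- surface$vertices; f <- surface$faces
  sc <- surface$scalars
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z")
  for (nm in names(sc)) hdr <- c(hdr, sprintf("property float %s", nm))
  hdr <- c(hdr, sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  vm <- v
  for (nm in names(sc)) vm <- cbind(vm, sc[[nm]])
  writeLines(apply(vm, 1, function(p) paste(fmt_num(p), collapse = " ")), con)
  writeLines(paste(3, f[, 1] - 1, f[, 2] - 1, f[, 3] - 1), con)
  invisible(path)
}

#' Read an ASCII PLY triangle surface
#' @param path PLY file
#' @return a `tri_surface` (extra vertex properties land in `scalars`)
#' @export
read_ply_surface <- function(path) {
  ln <- trimws(readLines(path))
  endh <- grep("^end_header", ln)[1]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", ln, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face", ln, value = TRUE)[1]))
  iv <- grep("^element vertex", ln)[1]
  if_ <- grep("^element face", ln)[1]
  props <- sub("property float ", "", grep("^property float", ln[iv:if_], value = TRUE))
  vdat <- matrix(as.numeric(unlist(strsplit(ln[(endh + 1):(endh + nv)], " +"))),
                 ncol = length(props), byrow = TRUE)
  fdat <- matrix(as.integer(unlist(strsplit(ln[(endh + nv + 1):(endh + nv + nf)], " +"))),
                 ncol = 4, byrow = TRUE)
  sc <- list()
  if (length(props) > 3)
    for (k in 4:length(props)) sc[[props[k]]] <- vdat[, k]
  new_tri_surface(vdat[, 1:3, drop = FALSE], fdat[, 2:4, drop = FALSE] + 1L,
                  scalars = sc)
}

#' Write an image phantom as multi-page TIFF plus a JSON sidecar
#'
#' The TIFF holds one 32-bit float page per z-slice; the sidecar
#' (`<path>.json`) records voxel size and the ground truth (surfaces, cells).
#' @param phantom an `image_phantom`
#' @param path output TIFF path
#' @return the path, invisibly
#' @export
write_phantom_tiff <- function(phantom, path) {
  pages <- lapply(seq_len(dim(phantom$stack)[3]), function(k) {
    # TIFF pages are row-major images: rows = y, cols = x
    t(phantom$stack[, , k])
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  side <- list(voxel_size = phantom$voxel_size,
               shape = dim(phantom$stack),
               truth_outer_surface = phantom$truth_outer_surface,
               truth_inner_surface = phantom$truth_inner_surface,
               truth_cells = phantom$truth_cells,
               meta = phantom$meta[setdiff(names(phantom$meta), "levels")])
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack
#' @param path TIFF file
#' @return 3D array `(x, y, z)`; if a `<path>.json` sidecar exists it is
#'   attached as the `sidecar` attribute
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
  side <- paste0(path, ".json")
  if (file.exists(side))
    attr(arr, "sidecar") <- jsonlite::read_json(side, simplifyVector = TRUE)
  arr
}

#' Write indentation curves as CSV files with a JSON probe header
#'
#' Each curve becomes `curve_###.csv` (columns `displacement_um`,
#' `force_uN`); probe metadata goes to `probe.json` in the same directory.
#' @param curves list of `indentation_curve`
#' @param dir output directory (created if missing)
#' @return the directory, invisibly
#' @export
write_indentation_csv <- function(curves, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(curves)) {
    cu <- curves[[i]]
    write.csv(data.frame(displacement_um = cu$displacement,
                         force_uN = cu$force),
              file.path(dir, sprintf("curve_%03d.csv", i)), row.names = FALSE)
  }
  jsonlite::write_json(list(probe_radius_um = curves[[1]]$probe_radius,
                            truth_modulus_pa = curves[[1]]$truth_modulus,
                            n_curves = length(curves)),
                       file.path(dir, "probe.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read indentation curves written by [write_indentation_csv()]
#' @param dir directory containing `curve_*.csv` and `probe.json`
#' @return list of `indentation_curve`
#' @export
read_indentation_csv <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "probe.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^curve_\\d+\\.csv$",
                           full.names = TRUE))
  lapply(seq_along(files), function(i) {
    df <- read.csv(files[i])
    structure(list(displacement = df$displacement_um, force = df$force_uN,
                   probe_radius = meta$probe_radius_um,
                   truth_modulus = meta$truth_modulus_pa, curve_id = i),
              class = "indentation_curve")
  })
}

#' Write a fold network as an edge-list CSV
#' @param surface the `tri_surface` the network was extracted from
#' @param network a `fold_network`
#' @param path output CSV
#' @return the path, invisibly
#' @export
write_fold_network_csv <- function(surface, network, path) {
  e <- network$crease_edges
  if (nrow(e)) {
    len <- sqrt(rowSums((surface$vertices[e[, 1], , drop = FALSE] -
                         surface$vertices[e[, 2], , drop = FALSE])^2))
    remap <- integer(nrow(surface$vertices))
    remap[network$crease_vertices] <- network$component
    df <- data.frame(v1 = e[, 1], v2 = e[, 2], length = len,
                     component = remap[e[, 1]],
                     open = network$component_open[remap[e[, 1]]])
  } else {
    df <- data.frame(v1 = integer(0), v2 = integer(0), length = numeric(0),
                     component = integer(0), open = logical(0))
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
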