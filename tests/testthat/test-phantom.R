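# Image phantoms and synthetic indentation curves: ground-truth contracts.

test_that("noiseless cell-free phantom is a deterministic two-band dome", {
  p1 <- make_image_phantom(n_cells = 0, noise_sd = 0, seed = 1)
  p2 <- make_image_phantom(n_cells = 0, noise_sd = 0, seed = 99)
  expect_identical(p1$stack, p2$stack)        # no stochastic element left
  expect_true(all(p1$stack >= 0 & p1$stack <= 1))
  # zero intensity outside the tissue (above the dome apex)
  expect_equal(max(p1$stack[, , dim(p1$stack)[3]]), 0)
  # nested truth surfaces
  expect_lt(p1$truth_inner_surface$radius, p1$truth_outer_surface$radius)
})

test_that("cells are placed with the required separation and recorded exactly", {
  p <- make_image_phantom(n_cells = 20, noise_sd = 0, seed = 3)
  expect_equal(nrow(p$truth_cells), 20)
  d <- as.matrix(dist(p$truth_cells))
  diag(d) <- Inf
  expect_gt(min(d), 2 * p$meta$cell_radius)
  # impossible packing errors out naming the failing count
  expect_error(make_image_phantom(n_cells = 3000, seed = 1), "3000")
})

test_that("noisy phantoms are voxelwise reproducible under a fixed seed", {
  a <- make_image_phantom(n_cells = 10, noise_sd = 0.05, seed = 7)
  b <- make_image_phantom(n_cells = 10, noise_sd = 0.05, seed = 7)
  expect_identical(a$stack, b$stack)
  c2 <- make_image_phantom(n_cells = 10, noise_sd = 0.05, seed = 8)
  expect_false(identical(a$stack, c2$stack))
})

test_that("blob intensity integral is constant across cells", {
  pc <- make_image_phantom(n_cells = 15, noise_sd = 0, seed = 5)
  p0 <- make_image_phantom(n_cells = 0, noise_sd = 0, seed = 5)
  blob <- pc$stack - p0$stack          # cells only (clipping margin respected)
  # assign blob mass to the nearest cell (windows of nearby cells overlap)
  vox <- mask_to_points(blob > 1e-6)
  w <- blob[blob > 1e-6]
  d2 <- sapply(seq_len(nrow(pc$truth_cells)), function(k) {
    rowSums(sweep(vox, 2, pc$truth_cells[k, ])^2)
  })
  nearest <- max.col(-d2)
  sums <- vapply(seq_len(nrow(pc$truth_cells)),
                 function(k) sum(w[nearest == k]), 0)
  expect_lt(sd(sums) / mean(sums), 0.05)
  # and the mass matches the analytic Gaussian integral A (2 pi)^(3/2) sigma^3
  sig <- pc$meta$cell_radius / 2
  expect_equal(mean(sums), 0.4 * (2 * pi)^1.5 * sig^3, tolerance = 0.02)
})

test_that("thresholding the noiseless phantom recovers the layer thicknesses within a voxel", {
  p <- make_image_phantom(h_epid = 4, h_dermis = 12, n_cells = 0,
                          noise_sd = 0, seed = 1)
  lv <- p$meta$levels
  d <- dim(p$stack)
  ctr <- p$truth_outer_surface$center
  xs <- (0:(d[1] - 1)) - ctr[1]; ys <- (0:(d[2] - 1)) - ctr[2]
  zs <- (0:(d[3] - 1)) - ctr[3]
  r <- sqrt(outer(outer(xs^2, ys^2, "+"), zs^2, "+"))
  up <- r[p$stack > (lv[["epidermis"]] + lv[["dermis"]]) / 2]
  expect_lt(abs((max(up) - min(up)) - p$meta$h_epid), 1)
  skin <- r[p$stack > (lv[["dermis"]] + lv[["bone"]]) / 2]
  expect_lt(abs((max(skin) - min(skin)) - (p$meta$h_epid + p$meta$h_dermis)), 1)
})

test_that("phantom TIFF + sidecar round trip preserves the stack and truth", {
  p <- make_image_phantom(shape = c(40, 40, 32), h_epid = 3, h_dermis = 6,
                          n_cells = 5, noise_sd = 0.02, seed = 2)
  tf <- tempfile(fileext = ".tif")
  write_phantom_tiff(p, tf)
  arr <- read_stack_tiff(tf)
  expect_equal(dim(arr), dim(p$stack))
  expect_equal(arr, p$stack, tolerance = 1e-6, ignore_attr = TRUE)
  side <- attr(arr, "sidecar")
  expect_equal(side$truth_outer_surface$radius, p$truth_outer_surface$radius)
  expect_equal(nrow(side$truth_cells), 5)
  unlink(c(tf, paste0(tf, ".json")))
})

test_that("noiseless indentation curves equal the Hertz forward model exactly", {
  cu <- make_indentation_curves(E_true = 1e5, probe_radius = 99, max_depth = 2,
                                n_curves = 1, noise_sd = 0, seed = 1)[[1]]
  expect_equal(cu$force, hertz_force(cu$displacement, 1e5, 99))
  expect_equal(cu$force[1], 0)
  expect_true(all(diff(cu$displacement) > 0))
  # terminal force of the published protocol geometry
  expect_equal(tail(cu$force, 1), (4 / 3) * 1e5 * sqrt(99) * 2^1.5 * 1e-6,
               tolerance = 1e-12)
  expect_equal(tail(cu$force, 1), 3.75, tolerance = 0.01)
})

test_that("curve batches have distinct noise but shared truth, and the Hertz regime is enforced", {
  cus <- make_indentation_curves(1e5, 99, 2, n_curves = 30, noise_sd = 0.01,
                                 seed = 4)
  expect_length(cus, 30)
  expect_true(all(vapply(cus, function(c) c$truth_modulus, 0) == 1e5))
  expect_gt(length(unique(vapply(cus, function(c) tail(c$force, 1), 0))), 25)
  expect_error(make_indentation_curves(1e5, 99, 10), "Hertz")
  expect_error(hertz_force(-0.1, 1e5, 99), "nonnegative")
})
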