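# Hertzian indentation analysis: forward model, fitting, filtering.

test_that("the Hertz forward model obeys its power law and protocol value", {
  expect_equal(hertz_force(0, 1e5, 99), 0)
  # F(2 delta) / F(delta) = 2 sqrt(2)
  expect_equal(hertz_force(2, 1e5, 99) / hertz_force(1, 1e5, 99), 2 * sqrt(2),
               tolerance = 1e-12)
  expect_equal(hertz_force(2, 1e5, 99), 3.752, tolerance = 1e-3)
})

test_that("noiseless fits recover the modulus exactly with unit fit quality", {
  cu <- make_indentation_curves(1e5, 99, 2, n_curves = 1, noise_sd = 0)[[1]]
  r <- fit_hertz(cu)
  expect_equal(r$E_eff, 1e5, tolerance = 1e-9)
  expect_equal(r$fit_quality, 1)
})

test_that("the unit audit: m/N inputs give the same modulus in Pa", {
  cu <- make_indentation_curves(2e5, 99, 2, n_curves = 1, noise_sd = 0)[[1]]
  # convert um -> m and uN -> N; the Hertz fit is unit-consistent if R, delta
  # and F share a length/force system: E[Pa] = 3 F / (4 sqrt(R) d^1.5)
  k_um <- fit_hertz(cu)$E_eff
  cu_m <- cu
  cu_m$displacement <- cu$displacement * 1e-6
  cu_m$force <- cu$force * 1e-6
  cu_m$probe_radius <- cu$probe_radius * 1e-6
  d <- cu_m$displacement[-1]; f <- cu_m$force[-1]
  k_m <- median(3 * f / (4 * sqrt(cu_m$probe_radius) * d^1.5))
  expect_equal(k_m, k_um, tolerance = 1e-9)
})

test_that("median recovered modulus is within 2% of truth at 1% noise, and bias shrinks with noise", {
  fitall <- function(noise, seed) {
    cus <- make_indentation_curves(1e5, 99, 2, n_curves = 30, noise_sd = noise,
                                   seed = seed)
    vapply(seq_along(cus), function(i) fit_hertz(cus[[i]])$E_eff, 0)
  }
  e1 <- fitall(0.01, 42)
  expect_lt(abs(median(e1) - 1e5) / 1e5, 0.02)
  # estimator consistency: error shrinks as noise -> 0
  err <- vapply(c(0.1, 0.01, 0.001), function(ns) {
    abs(median(fitall(ns, 7)) - 1e5) / 1e5
  }, 0)
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 1e-3)
})

test_that("pure-noise curves fall far below the retention threshold", {
  cu <- make_indentation_curves(1e5, 99, 2, n_curves = 1, noise_sd = 0)[[1]]
  withr::with_seed(3, {
    cu$force <- abs(rnorm(length(cu$force), 0, 1))
  })
  r <- fit_hertz(cu)
  expect_lt(r$fit_quality, 0.5)
  # non-monotone displacement is rejected
  bad <- cu
  bad$displacement[5] <- bad$displacement[7]
  expect_error(fit_hertz(bad), "increasing")
})

test_that("filtering and aggregation respect the grid protocol and the inclusive threshold", {
  mkres <- function(rep, n, E, q) {
    lapply(seq_len(n), function(i) {
      structure(list(E_eff = E[i], fit_quality = q[i], contact_offset = 0,
                     curve_id = i, replicate_id = rep, grid_position = i),
                class = "indentation_result")
    })
  }
  # all perfect: n_retained equals the grid size
  res <- mkres(1, 30, rep(1e5, 30), rep(1, 30))
  agg <- filter_and_aggregate(res, min_quality = 0.95, grid = c(3, 10))
  expect_equal(agg$n_retained, 30L)
  expect_equal(agg$sd_E, 0)                       # identical values: SD = 0
  # boundary: 0.94 dropped, 0.95 retained (inclusive)
  res2 <- mkres(1, 9, c(2e5, rep(1e5, 8)), c(0.94, 0.95, rep(1, 7)))
  agg2 <- filter_and_aggregate(res2, min_quality = 0.95, grid = c(3, 3))
  expect_equal(agg2$n_retained, 8L)
  expect_equal(agg2$mean_E, 1e5)
  # zero retained flagged missing
  res3 <- mkres(1, 9, rep(1e5, 9), rep(0.5, 9))
  agg3 <- filter_and_aggregate(res3, min_quality = 0.95, grid = c(3, 3))
  expect_true(agg3$missing)
  expect_equal(agg3$n_retained, 0L)
  # grid-size mismatch is an error
  expect_error(filter_and_aggregate(res2, grid = c(3, 10)), "grid")
})

test_that("contact-offset pre-fit recovers a shifted contact point", {
  cu <- make_indentation_curves(1e5, 99, 2, n_curves = 1, noise_sd = 0,
                                n_points = 200)[[1]]
  shifted <- cu
  d0 <- 0.3
  shifted$force <- hertz_force(pmax(cu$displacement - d0, 0), 1e5, 99)
  plain <- fit_hertz(shifted)
  off <- fit_hertz(shifted, estimate_offset = TRUE)
  expect_lt(abs(off$contact_offset - d0), 0.05)
  expect_lt(abs(off$E_eff - 1e5) / 1e5, 0.05)
  expect_gt(off$fit_quality, plain$fit_quality)
})

test_that("indentation curve CSV round trip preserves data and probe metadata", {
  cus <- make_indentation_curves(1.3e5, 99, 2, n_curves = 3, noise_sd = 0.02,
                                 seed = 9)
  dir <- tempfile()
  write_indentation_csv(cus, dir)
  back <- read_indentation_csv(dir)
  expect_length(back, 3)
  expect_equal(back[[2]]$force, cus[[2]]$force, tolerance = 1e-6)
  expect_equal(back[[1]]$probe_radius, 99)
  expect_equal(back[[1]]$truth_modulus, 1.3e5)
  unlink(dir, recursive = TRUE)
})
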