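# Map-level pipeline: substrate, flattening, masking, bands, orchestration.

make_processed_map <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      vc <- small_cell()
      sim <- simulate_force_volume(vc, noise_sd = 10, seed = 3, n_points = 256)
      cache <<- list(sim = sim, res = process_force_volume(sim$map),
                     vc = vc)
    }
    cache
  }
})

test_that("substrate identification matches the generator's truth mask", {
  x <- make_processed_map()
  expect_identical(x$res$substrate, x$sim$truth$payload$substrate_mask)
  # threshold Inf leaves nothing
  expect_warning(
    s <- identify_substrate(x$res$modulus_pass1_pa, x$res$status, Inf),
    "no substrate")
  expect_false(any(s))
})

test_that("flattening recovers heights and zeroes the substrate under stage tilt", {
  vc <- small_cell()
  sim <- simulate_force_volume(vc, noise_sd = 0, seed = 5, n_points = 256,
                               tilt = c(12, -7))
  res <- process_force_volume(sim$map)
  truth_h <- sim$truth$payload$height_map
  err <- (res$height_um - truth_h)[res$mask]
  expect_lt(sqrt(mean(err^2)) / sqrt(mean(truth_h[res$mask]^2)), 0.01)
  expect_true(all(abs(res$height_um[res$substrate]) < 0.01))  # < 10 nm
  # the recovered plane carries the injected tilt
  expect_equal(attr(res$height_um, "plane")[2], 12, tolerance = 0.01)
  expect_equal(attr(res$height_um, "plane")[3], -7, tolerance = 0.01)
})

test_that("flattening requires three non-collinear substrate pixels", {
  z0 <- matrix(1000, 8, 8)
  sub <- matrix(FALSE, 8, 8)
  sub[1, 1:2] <- TRUE
  expect_error(flatten_heights(z0, sub), ">= 3 substrate")
  sub[1, 3] <- TRUE  # three collinear points
  expect_error(flatten_heights(z0, sub), "collinear")
})

test_that("cell mask equals a brute-force recount of the three criteria", {
  x <- make_processed_map()
  expect_identical(x$res$mask,
                   oracle_cell_mask(x$res$height_um, x$res$modulus_pass2_pa,
                                    x$res$status))
  # permissive limits admit every ok pixel
  all_ok <- build_cell_mask(x$res$height_um, x$res$modulus_pass2_pa,
                            x$res$status, min_height = 0,
                            stiff_threshold = Inf)
  expect_identical(all_ok, x$res$status %in% c("ok", "fallback") &
                     !is.na(x$res$height_um))
  # no usable curves -> empty mask
  st <- x$res$status; st[] <- "no_baseline"
  expect_false(any(build_cell_mask(x$res$height_um, x$res$modulus_pass2_pa, st)))
})

test_that("band statistics reproduce the periphery stiffening factor", {
  x <- make_processed_map()
  b <- x$res$band_stats
  expect_identical(nrow(b), 2L)
  ratio <- b$mean_modulus_pa[b$lo_um == 0] / b$mean_modulus_pa[b$lo_um == 2]
  expect_equal(ratio, 1.6, tolerance = 0.05)
  # uniform modulus map -> equal band means
  u <- band_statistics(x$res$height_um, matrix(5e3, 16, 16), x$res$mask)
  expect_equal(u$mean_modulus_pa[1], u$mean_modulus_pa[2])
  # an impossible band is NaN with zero count, not an error
  hi <- band_statistics(x$res$height_um, x$res$modulus_pass2_pa, x$res$mask,
                        bands = list(c(10, 20)))
  expect_identical(hi$n_pixels, 0L)
  expect_true(is.nan(hi$mean_modulus_pa))
})

test_that("end-to-end modulus recovery is accurate and deterministic", {
  x <- make_processed_map()
  rel <- (x$res$modulus_pass2_pa - x$sim$truth$payload$modulus_map) /
    x$sim$truth$payload$modulus_map
  expect_lt(sqrt(mean(rel[x$res$mask]^2)), 0.05)
  rerun <- process_force_volume(x$sim$map)
  expect_identical(rerun$modulus_pass2_pa, x$res$modulus_pass2_pa)
  expect_identical(rerun$mask, x$res$mask)
})

test_that("substrate-only map yields empty mask and bands without crashing", {
  vc <- make_virtual_cell(c(8, 8), cell_radius = 3, max_height = 2,
                          e_cell = 1e4, pixel_size = 1)
  vc$height_map[] <- 0                 # flatten the cell away
  vc$modulus_map[] <- vc$substrate_modulus
  sim <- simulate_force_volume(vc, noise_sd = 0, seed = 2, n_points = 128)
  res <- process_force_volume(sim$map)
  expect_false(any(res$mask))
  expect_true(all(res$band_stats$n_pixels == 0))
})

test_that("no-substrate map fails cleanly", {
  vc <- small_cell(c(12, 12))
  sim <- simulate_force_volume(vc, noise_sd = 0, seed = 2, n_points = 128)
  # pretend every pixel is soft cell: raise the stiffness threshold
  expect_error(
    suppressWarnings(process_force_volume(
      sim$map, fv_config(stiff_threshold_pa = 1e9))),
    "substrate")
})
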