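# Morphometric and kinetic summaries.

test_that("traction summary satisfies total = mean x area for uniform fields", {
  mask <- matrix(FALSE, 9, 9); mask[3:7, 3:7] <- TRUE
  f <- simulate_traction_field(mask, 100, "uniform", 1, 0, 1)$field
  s <- traction_summary(f, margin_um = 0)
  expect_equal(s$total_force_nn, 2.5)
  expect_equal(s$mean_stress_pa, 100)
  expect_equal(s$area_um2, 25)
  expect_equal(s$total_force_nn, s$mean_stress_pa * s$area_um2 / 1e3)
  # doubling the spacing quadruples the force, mean unchanged
  f2 <- f; f2$grid_spacing <- 2
  s2 <- traction_summary(f2, margin_um = 0)
  expect_equal(s2$total_force_nn, 4 * s$total_force_nn)
  expect_equal(s2$mean_stress_pa, s$mean_stress_pa)
  # margin dilation preserves the identity for uniform-magnitude regions
  sm <- traction_summary(f, margin_um = 2)
  expect_equal(sm$total_force_nn, sm$mean_stress_pa * sm$area_um2 / 1e3)
  expect_gt(sm$area_um2, s$area_um2)
  # zero field
  f0 <- f; f0$tx[] <- 0; f0$ty[] <- 0
  expect_equal(traction_summary(f0, 0)$total_force_nn, 0)
})

test_that("FRET ratio is the YFP/CFP pooled-intensity ratio", {
  cfp <- matrix(c(2, 2, 1, 3), 2)
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  expect_equal(fret_ratio(cfp, cfp, mask)$ratio, 1)
  expect_equal(fret_ratio(2 * cfp, cfp, mask)$ratio, 2)
  yfp <- matrix(c(4, 6, 0, 0), 2)
  expect_equal(fret_ratio(yfp, matrix(c(2, 2, 1, 1), 2), mask)$ratio, 2.5)
  expect_error(fret_ratio(yfp, matrix(0, 2, 2), mask), "zero")
  # donor-zero pixels are flagged in the ratio image
  cz <- cfp; cz[1, 1] <- 0
  r <- fret_ratio(yfp, cz)
  expect_true(is.na(r$ratio_image[1, 1]) && r$n_cfp_zero == 1)
})

test_that("CTCF follows integrated density minus area-scaled background", {
  img <- matrix(1, 10, 10)
  cell <- matrix(FALSE, 10, 10); cell[1:2, 1:5] <- TRUE   # 10 px
  img[cell] <- 5
  bg <- matrix(FALSE, 10, 10); bg[8:10, 8:10] <- TRUE
  expect_equal(corrected_total_fluorescence(img, cell, bg), 50 - 10 * 1)
  # zero background -> integrated density
  img0 <- img; img0[bg] <- 0
  expect_equal(corrected_total_fluorescence(img0, cell, bg), 50)
  # image at background level -> 0
  expect_equal(corrected_total_fluorescence(matrix(3, 10, 10), cell, bg), 0)
  expect_error(corrected_total_fluorescence(img, cell, cell), "disjoint")
  expect_error(corrected_total_fluorescence(img, cell & FALSE, bg),
               "non-empty")
})

test_that("shape metrics: ellipse aspect ratio and centroid distance", {
  d <- disk_mask(61, 25)
  nuc <- disk_mask(61, 6)
  m <- shape_metrics(d, nuc, pixel_size = 0.5)
  expect_lte(m$aspect_ratio, 1.02)
  expect_gte(m$aspect_ratio, 1)
  expect_equal(m$nucleus_centroid_distance, 0, tolerance = 1e-9)
  # 40 x 10 rectangle: second moments give exactly ratio 4 in the continuum
  rect <- matrix(FALSE, 60, 60); rect[11:50, 26:35] <- TRUE
  mr <- shape_metrics(rect, rect, 1)
  expect_equal(mr$aspect_ratio, 4, tolerance = 0.03)
  # rotation invariance within discretization
  theta <- pi / 7
  n <- 121; ctr <- 61
  idx <- expand.grid(r = 1:n, c = 1:n)
  u <- (idx$r - ctr) * cos(theta) + (idx$c - ctr) * sin(theta)
  v <- -(idx$r - ctr) * sin(theta) + (idx$c - ctr) * cos(theta)
  rot <- matrix(abs(u) <= 20 & abs(v) <= 5, n, n)
  mrot <- shape_metrics(rot, rot, 1)
  expect_equal(mrot$aspect_ratio, 4, tolerance = 0.08)
  expect_error(shape_metrics(matrix(FALSE, 3, 3), d[1:3, 1:3]), "degenerate")
})

test_that("track metrics: path, net displacement, speed", {
  tr <- data.frame(t_s = c(0, 60, 120, 180),
                   x_um = c(0, 2, 4, 6), y_um = 0)
  m <- track_metrics(tr)
  expect_equal(m$path_length_um, 6)
  expect_equal(m$net_displacement_um, 6)
  expect_equal(m$mean_speed_um_min, 2)
  # closed square loop
  sq <- data.frame(t_s = 0:4, x_um = c(0, 1, 1, 0, 0),
                   y_um = c(0, 0, 1, 1, 0))
  ms <- track_metrics(sq)
  expect_equal(ms$net_displacement_um, 0)
  expect_equal(ms$path_length_um, 4)
  st <- data.frame(t_s = c(0, 10), x_um = c(1, 1), y_um = c(2, 2))
  expect_equal(track_metrics(st)$path_length_um, 0)
  expect_error(track_metrics(data.frame(t_s = c(0, 0), x_um = 1:2,
                                        y_um = 1:2)), "increasing")
})

test_that("nearest-neighbour linker keeps tracks separate and complete", {
  # two slow vesicles far apart, 10 frames
  det <- do.call(rbind, lapply(0:9, function(f)
    data.frame(frame = f, row = c(10 + 0.3 * f, 40 - 0.2 * f),
               col = c(10, 40))))
  tr <- link_detections(det, max_step = 5)
  expect_identical(length(unique(tr$track_id)), 2L)
  expect_true(all(table(tr$track_id) == 10))
  # each track stays on its own side
  t1 <- tr[tr$track_id == tr$track_id[which(tr$row < 25)[1]], ]
  expect_true(all(t1$row < 25))
  # steps beyond max_step start new tracks
  jump <- data.frame(frame = c(0, 1), row = c(0, 50), col = c(0, 50))
  expect_identical(length(unique(link_detections(jump, 5)$track_id)), 2L)
})

test_that("linker recovers simulated trajectories at low step noise", {
  mask <- matrix(FALSE, 60, 60); mask[25:35, 25:35] <- TRUE
  sim <- simulate_vesicle_movie(15, 1, mask,
                                list(list(c(4, 8)), list(c(10, 12))),
                                step_sd = 0.5, seed = 21)
  tr <- link_detections(sim$detections, max_step = 8)
  expect_identical(length(unique(tr$track_id)), 2L)
  expect_true(all(table(tr$track_id) == 15))
})

test_that("residence times equal the generator's ground truth", {
  mask <- matrix(FALSE, 50, 50); mask[20:32, 20:32] <- TRUE
  iv <- list(list(c(2, 6), c(10, 13)), list(c(0, 4)))
  sim <- simulate_vesicle_movie(16, frame_interval = 1,
                                compartment_mask = mask,
                                contact_intervals = iv, step_sd = 1, seed = 8)
  rec <- residence_times(sim$detections, mask, frame_interval = 1)
  got <- split(rec$duration_s, rec$track_id)
  expect_equal(unname(got[["1"]]), c(5, 4))
  expect_equal(unname(got[["2"]]), c(5))
  expect_equal(rec$enter_frame[rec$track_id == 2], 0)
  # sum of residences never exceeds track duration
  expect_true(all(tapply(rec$duration_s, rec$track_id, sum) <= 16))
  # never inside -> empty record
  off <- sim$detections; off$row <- 2; off$col <- 2
  expect_identical(nrow(residence_times(off, mask)), 0L)
  # positions off the raster are an input error
  bad <- sim$detections; bad$row[1] <- 99
  expect_error(residence_times(bad, mask), "outside")
})
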