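# Segmentation and Manders colocalization.

test_that("channel normalization maps ranges to [0,1] and is idempotent", {
  m <- matrix(c(10, 12, 15, 20), 2)
  n <- normalize_channel(m)
  expect_equal(range(n), c(0, 1))
  expect_equal(n[2, 1], 0.2)           # (12-10)/10
  expect_equal(normalize_channel(n), n)
  expect_true(all(normalize_channel(matrix(7, 3, 3)) == 0))
})

test_that("Phansalkar threshold matches the hand value on a uniform image", {
  img <- matrix(0.5, 20, 20)
  # t = 0.5 (1 + 2 e^{-5} - 0.25) = 0.3817379; everything is foreground
  expect_true(all(phansalkar_threshold(img)))
  st <- 0.5 * (1 + 2 * exp(-5) + 0.25 * (0 / 0.5 - 1))
  expect_equal(st, 0.38174, tolerance = 1e-4)
  # all-zero image: threshold 0 is never strictly exceeded
  expect_false(any(phansalkar_threshold(matrix(0, 20, 20))))
})

test_that("Phansalkar mask is pixel-identical to the brute-force oracle", {
  set.seed(42)
  for (i in 1:3) {
    img <- normalize_channel(matrix(runif(32 * 32), 32))
    expect_identical(phansalkar_threshold(img), oracle_phansalkar(img))
  }
  # non-default parameters too
  img <- normalize_channel(matrix(rexp(32 * 32), 32))
  pp <- threshold_params(window = 7, k_p = 0.3, r_p = 0.4, p_p = 3, q_p = 8)
  expect_identical(phansalkar_threshold(img, pp),
                   oracle_phansalkar(img, 7, 0.3, 0.4, 3, 8))
  expect_error(threshold_params(window = 8), "odd")
})

test_that("median filter matches the oracle and removes speckle", {
  set.seed(7)
  m <- matrix(runif(30 * 30) > 0.5, 30)
  expect_identical(median_filter_mask(m, 16), oracle_median_mask(m, 5))
  expect_identical(median_filter_mask(m, 7, "side"), oracle_median_mask(m, 7))
  expect_identical(median_filter_mask(m, 2, "radius"), oracle_median_mask(m, 5))
  # isolated pixel removed, solid block interior kept
  sp <- matrix(FALSE, 21, 21); sp[11, 11] <- TRUE
  expect_false(any(median_filter_mask(sp, 16)))
  blk <- matrix(FALSE, 21, 21); blk[5:17, 5:17] <- TRUE
  expect_true(all(median_filter_mask(blk, 16)[7:15, 7:15]))
  expect_error(median_filter_mask(sp, 0), "neighborhood")
})

test_that("Manders split reproduces the printed-formula hand example", {
  s1 <- c(2, 3, 0); s2 <- c(1, 0, 4)
  r <- manders_split(s1, s2, s1 > 0, s2 > 0)
  expect_equal(r$m1, 0.4)
  expect_equal(r$m2, 0.2)
  # identical channels
  ri <- manders_split(s1, s1, s1 > 0, s1 > 0)
  expect_equal(c(ri$m1, ri$m2), c(1, 1))
  # disjoint masks
  rd <- manders_split(s1, s2, c(TRUE, FALSE, FALSE), c(FALSE, FALSE, TRUE))
  expect_equal(c(rd$m1, rd$m2), c(0, 0))
  # empty denominator flagged as NaN
  rn <- manders_split(s1, s2, rep(FALSE, 3), s2 > 0)
  expect_true(is.nan(rn$m1) && rn$empty_denominator)
  expect_error(manders_split(s1, c(1, 2), s1 > 0, c(TRUE, TRUE)), "shape")
})

test_that("M1 is invariant to rescaling channel 1 at fixed masks", {
  set.seed(11)
  s1 <- matrix(rexp(100), 10); s2 <- matrix(rexp(100), 10)
  m1 <- s1 > 0.5; m2 <- s2 > 0.5
  a <- manders_split(s1, s2, m1, m2)
  b <- manders_split(s1 * 37.5, s2, m1, m2)
  expect_equal(a$m1, b$m1)
  expect_equal(a$m2, b$m2)
})

test_that("conjunction mask is the logical AND", {
  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  b <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2)
  expect_identical(conjunction_mask(a, b), a & b)
  expect_identical(conjunction_mask(a, a), a)
  expect_equal(sum(conjunction_mask(a, b)), 1)
})

test_that("pipeline recovers total and zero overlap on synthetic stacks", {
  hi <- simulate_coloc_stack(overlap_fraction = 1, noise_sd = 0, seed = 4)
  r_hi <- coloc_pipeline(hi$stack, c("ch1", "ch2"))
  expect_gte(r_hi$m1, 0.95)
  expect_gte(r_hi$m2, 0.95)
  lo <- simulate_coloc_stack(overlap_fraction = 0, noise_sd = 0, seed = 4)
  r_lo <- coloc_pipeline(lo$stack, c("ch1", "ch2"))
  expect_lte(r_lo$m1, 0.05)
  expect_lte(r_lo$m2, 0.05)
  expect_error(coloc_pipeline(hi$stack, c("ch1", "nope")), "unknown channel")
})

test_that("requested overlap fraction is recorded in truth after rounding", {
  sim <- simulate_coloc_stack(overlap_fraction = 0.5,
                              n_vesicles_per_channel = 40, seed = 2)
  expect_equal(unname(sim$truth$payload$n_shared), 20)
  expect_equal(unname(sim$truth$payload$overlap_fraction[["ch1_ch2"]]), 0.5)
  tri <- simulate_coloc_stack(overlap_fraction = 0.25, n_channels = 3, seed = 2)
  expect_named(tri$truth$payload$overlap_fraction, c("ch1_ch2", "ch1_ch3"))
  expect_length(tri$stack$channels, 3)
})

test_that("many small objects inside one large object give M1 >> M2", {
  # channel 1: small puncta scattered inside channel 2's single large blob
  n <- 99
  s2 <- matrix(0, n, n)
  s2[20:80, 20:80] <- 100
  s1 <- matrix(0, n, n)
  set.seed(9)
  ctr <- cbind(sample(25:75, 8), sample(25:75, 8))
  for (k in 1:8)
    s1[ctr[k, 1] + (-2:2), ctr[k, 2] + (-2:2)] <- 100
  st <- image_stack(list(puncta = s1, blob = s2), 0.1)
  r <- coloc_pipeline(st, c("puncta", "blob"))
  expect_gte(r$m1, 0.9)
  expect_lt(r$m2, 0.3)
  expect_gt(r$m1 - r$m2, 0.5)
})
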