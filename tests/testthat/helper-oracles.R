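# Independent brute-force oracles. These re-derive results per pixel with
# plain loops, deliberately sharing no code with the package internals.

# Edge-replicated window of side w centred at (i, j).
oracle_window <- function(img, i, j, r) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- pmin(pmax((i - r):(i + r), 1), nr)
  ci <- pmin(pmax((j - r):(j + r), 1), nc)
  img[ri, ci, drop = FALSE]
}

# Per-pixel Phansalkar threshold mask by direct formula evaluation.
oracle_phansalkar <- function(img, window = 15, k = 0.25, r = 0.5,
                              p = 2, q = 10) {
  rad <- (window - 1) / 2
  out <- matrix(FALSE, nrow(img), ncol(img))
  for (i in seq_len(nrow(img))) {
    for (j in seq_len(ncol(img))) {
      w <- oracle_window(img, i, j, rad)
      m <- mean(w)
      s <- sqrt(mean((w - m)^2))
      t <- m * (1 + p * exp(-q * m) + k * (s / r - 1))
      out[i, j] <- img[i, j] > t
    }
  }
  out
}

# Per-pixel sliding median of a binary mask (window side must be odd).
oracle_median_mask <- function(mask, side) {
  rad <- (side - 1) / 2
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      w <- oracle_window(mask, i, j, rad)
      out[i, j] <- stats::median(w) > 0.5
    }
  }
  out
}

# Brute-force recount of the three cell-mask criteria.
oracle_cell_mask <- function(heights_um, moduli_pa, statuses,
                             min_height_nm = 100, stiff_pa = 65e3) {
  out <- matrix(FALSE, nrow(heights_um), ncol(heights_um))
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(ncol(out))) {
      out[i, j] <- !is.na(heights_um[i, j]) &&
        heights_um[i, j] * 1000 >= min_height_nm &&
        !is.na(moduli_pa[i, j]) && moduli_pa[i, j] <= stiff_pa &&
        statuses[i, j] %in% c("ok", "fallback")
    }
  }
  out
}

# Small standard fixtures -----------------------------------------------

noiseless_curve <- function(e_pa = 1e4, h = Inf, slope = 0, n = 512,
                            seed = 1, ...) {
  simulate_force_curve(e_pa, h, probe_params(), baseline_slope = slope,
                       noise_sd = 0, n_points = n, seed = seed, ...)
}

small_cell <- function(shape = c(16, 16), factor = 1.6) {
  r <- min(6, min(shape) / 2 - 1)
  make_virtual_cell(shape, cell_radius = r, max_height = min(4, 2 * r),
                    e_cell = 1e4, e_periphery_factor = factor,
                    pixel_size = 1)
}

disk_mask <- function(n, r, centre = (n + 1) / 2) {
  d2 <- outer((seq_len(n) - centre)^2, (seq_len(n) - centre)^2, `+`)
  d2 <= r^2
}
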