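# Map-level force-volume analysis: substrate identification, topographic
# flattening, cell masking, height-band statistics and the two-pass
# orchestration.

#' Identify rigid-substrate pixels from first-pass moduli
#'
#' Pixels whose first-pass fit converged and whose apparent modulus exceeds
#' `stiff_threshold` are taken to be the bare plastic substrate; these anchor
#' the topographic flattening plane.
#'
#' @param moduli Matrix of first-pass apparent moduli, Pa.
#' @param statuses Character matrix of fit statuses (same shape).
#' @param stiff_threshold Modulus above which a pixel is substrate, Pa.
#' @return Logical matrix; `TRUE` marks substrate.
#' @export
identify_substrate <- function(moduli, statuses, stiff_threshold = 65e3) {
  stopifnot(identical(dim(moduli), dim(statuses)))
  sub <- statuses == "ok" & !is.na(moduli) & moduli > stiff_threshold
  if (!any(sub))
    warning("no substrate pixels found; flattening will fail", call. = FALSE)
  sub
}

#' Flatten contact points into a height map
#'
#' Least-squares plane through the first-pass contact points over substrate
#' pixels, removing stage tilt. The per-pixel height is the (signed) distance
#' from the plane to the contact point, in um, with cell pixels positive and
#' substrate pixels ~0. Small negative heights (fit noise on the substrate)
#' are clamped to 0; the clamp count is attached as an attribute.
#'
#' @param z0 Matrix of contact points, nm (piezo frame).
#' @param substrate Logical substrate matrix from [identify_substrate()].
#' @return Height matrix, um, with attributes `plane` (coefficients
#'   `c(intercept, row, col)` in nm) and `n_clamped`.
#' @export
flatten_heights <- function(z0, substrate) {
  stopifnot(identical(dim(z0), dim(substrate)))
  idx <- which(substrate & is.finite(z0))
  if (length(idx) < 3)
    stop("flattening error: need >= 3 substrate pixels with contact points",
         call. = FALSE)
  rc <- arrayInd(idx, dim(z0))
  X <- cbind(1, rc[, 1], rc[, 2])
  if (qr(X)$rank < 3)
    stop("flattening error: substrate pixels are collinear", call. = FALSE)
  fit <- stats::lm.fit(X, z0[idx])
  co <- fit$coefficients
  all_rc <- arrayInd(seq_along(z0), dim(z0))
  plane <- co[1] + co[2] * all_rc[, 1] + co[3] * all_rc[, 2]
  h <- matrix((plane - as.vector(z0)) / 1e3, nrow(z0), ncol(z0))
  n_clamped <- sum(h < 0, na.rm = TRUE)
  h[!is.na(h) & h < 0] <- 0
  attr(h, "plane") <- unname(co)
  attr(h, "n_clamped") <- n_clamped
  h
}

#' Build the analysis cell mask
#'
#' A pixel belongs to the cell mask iff its height is at least `min_height`
#' (excludes bare substrate and sub-resolution rims), its corrected modulus
#' is at most `stiff_threshold` (excludes substrate misclassified as cell),
#' and its curve fit succeeded (excludes curves without an identifiable
#' baseline or contact).
#'
#' @param heights Height matrix, um.
#' @param moduli Modulus matrix, Pa (second pass where available).
#' @param statuses Character status matrix.
#' @param min_height Minimum height, nm.
#' @param stiff_threshold Maximum modulus, Pa.
#' @return Logical matrix.
#' @export
build_cell_mask <- function(heights, moduli, statuses, min_height = 100,
                            stiff_threshold = 65e3) {
  stopifnot(identical(dim(heights), dim(moduli)),
            identical(dim(heights), dim(statuses)))
  !is.na(heights) & heights >= min_height / 1e3 &
    !is.na(moduli) & moduli <= stiff_threshold &
    statuses %in% c("ok", "fallback")
}

#' Mean modulus by height band
#'
#' Arithmetic mean of the (corrected) modulus over masked pixels whose height
#' falls in each band, lower edge inclusive, upper edge exclusive. The default
#' bands separate the thick cell body (2-5 um) from the thin periphery
#' (< 2 um).
#'
#' @param heights Height matrix, um.
#' @param moduli Modulus matrix, Pa.
#' @param mask Logical matrix restricting the statistics.
#' @param bands List of `c(lo, hi)` height ranges in um.
#' @return An object of class `band_stats`: data frame with `lo_um`, `hi_um`,
#'   `mean_modulus_pa`, `n_pixels`. Empty bands give `NaN` with count 0.
#' @export
band_statistics <- function(heights, moduli, mask,
                            bands = list(c(2, 5), c(0, 2))) {
  stopifnot(identical(dim(heights), dim(moduli)),
            identical(dim(heights), dim(mask)))
  rows <- lapply(bands, function(b) {
    sel <- mask & !is.na(heights) & heights >= b[1] & heights < b[2] &
      !is.na(moduli)
    n <- sum(sel)
    data.frame(lo_um = b[1], hi_um = b[2],
               mean_modulus_pa = if (n) mean(moduli[sel]) else NaN,
               n_pixels = n)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("band_stats", "data.frame")
  out
}

#' @export
print.band_stats <- function(x, ...) {
  cat("Height-band modulus statistics:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %.1f-%.1f um: %s kPa (n = %d)\n", x$lo_um[i], x$hi_um[i],
                format(x$mean_modulus_pa[i] / 1e3, digits = 4), x$n_pixels[i]))
  invisible(x)
}

#' Default force-volume processing configuration
#'
#' @param stiff_threshold_pa Substrate / mask modulus threshold, Pa.
#' @param min_height_nm Mask height threshold, nm.
#' @param max_indentation_nm Indentation cap for all fits, nm.
#' @param baseline_fraction Pre-contact fraction for baseline removal.
#' @param bands Height bands (um) for [band_statistics()].
#' @param z0_window_nm Pass-2 contact-point excursion, nm (0 = modulus only).
#' @param min_refit_height_um Below this height the bottom-effect refit is
#'   skipped and the first-pass result kept (the correction diverges as
#'   h -> 0 and such pixels are substrate by definition).
#' @return Named list of settings.
#' @export
fv_config <- function(stiff_threshold_pa = 65e3, min_height_nm = 100,
                      max_indentation_nm = 800, baseline_fraction = 0.3,
                      bands = list(c(2, 5), c(0, 2)), z0_window_nm = 20,
                      min_refit_height_um = 0.02) {
  list(stiff_threshold_pa = stiff_threshold_pa,
       min_height_nm = min_height_nm,
       max_indentation_nm = max_indentation_nm,
       baseline_fraction = baseline_fraction,
       bands = bands, z0_window_nm = z0_window_nm,
       min_refit_height_um = min_refit_height_um)
}

#' Two-pass analysis of a force-volume map
#'
#' Full processing chain for a grid of approach curves: virtual-deflection
#' baseline removal, first-pass linearized Hertz fit per pixel, substrate
#' identification (> 65 kPa by default), plane flattening of the substrate
#' contact points into a height map, second-pass bottom-effect refit at the
#' known local thickness, cell masking (height >= 100 nm, modulus <= 65 kPa,
#' usable baseline) and height-band modulus statistics.
#'
#' @param map A `force_volume` (see [simulate_force_volume()] or
#'   [read_force_volume()]).
#' @param config Settings from [fv_config()].
#' @return An object of class `force_volume_fit` with matrices `height_um`,
#'   `modulus_pass1_pa`, `modulus_pass2_pa`, `z0_nm`, `status` (character),
#'   `substrate`, `mask` (logical), plus `band_stats`, `exclusions` (named
#'   counts) and the `config` used.
#' @export
process_force_volume <- function(map, config = fv_config()) {
  stopifnot(inherits(map, "force_volume"))
  d <- dim(map$curves)
  nr <- d[1]; nc <- d[2]
  e1 <- z0 <- matrix(NA_real_, nr, nc)
  status <- matrix("excluded", nr, nc)
  fits1 <- vector("list", nr * nc); dim(fits1) <- d
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    cur <- correct_virtual_deflection(map$curves[[i, j]],
                                      config$baseline_fraction)
    f1 <- fit_hertz_linearized(cur, config$max_indentation_nm)
    fits1[[i, j]] <- f1
    status[i, j] <- f1$status
    if (f1$status == "ok") {
      e1[i, j] <- f1$apparent_modulus
      z0[i, j] <- f1$contact_point_z0
    }
  }
  substrate <- identify_substrate(e1, status, config$stiff_threshold_pa)
  heights <- flatten_heights(z0, substrate)
  e2 <- e1
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (status[i, j] != "ok" || substrate[i, j]) next
    h <- heights[i, j]
    if (is.na(h) || h < config$min_refit_height_um) next
    f2 <- fit_bottom_effect(fits1[[i, j]]$curve, h,
                            first_pass = fits1[[i, j]],
                            max_indentation = config$max_indentation_nm,
                            z0_window = config$z0_window_nm)
    e2[i, j] <- f2$apparent_modulus
    status[i, j] <- f2$status
  }
  mask <- build_cell_mask(heights, e2, status, config$min_height_nm,
                          config$stiff_threshold_pa)
  bands <- band_statistics(heights, e2, mask, config$bands)
  excl <- c(no_baseline = sum(status == "no_baseline"),
            no_contact = sum(status == "no_contact"),
            fallback = sum(status == "fallback"),
            clamped_heights = attr(heights, "n_clamped"))
  structure(
    list(height_um = heights, modulus_pass1_pa = e1, modulus_pass2_pa = e2,
         z0_nm = z0, status = status, substrate = substrate, mask = mask,
         band_stats = bands, exclusions = excl, config = config,
         pixel_size = map$pixel_size),
    class = "force_volume_fit")
}

#' @export
print.force_volume_fit <- function(x, ...) {
  d <- dim(x$height_um)
  cat(sprintf("force-volume analysis: %d x %d px, %d masked cell px\n",
              d[1], d[2], sum(x$mask)))
  cat(sprintf("  substrate px: %d; exclusions: %s\n", sum(x$substrate),
              paste(names(x$exclusions), x$exclusions, sep = "=",
                    collapse = ", ")))
  print(x$band_stats)
  invisible(x)
}

#' @export
summary.force_volume_fit <- function(object, ...) {
  m <- object$modulus_pass2_pa[object$mask]
  out <- list(n_masked = sum(object$mask),
              modulus_kpa = summary(m / 1e3),
              height_um = summary(object$height_um[object$mask]),
              band_stats = object$band_stats,
              exclusions = object$exclusions)
  class(out) <- "summary.force_volume_fit"
  out
}

#' @export
print.summary.force_volume_fit <- function(x, ...) {
  cat("Masked cell pixels:", x$n_masked, "\n")
  cat("Corrected modulus (kPa):\n"); print(x$modulus_kpa)
  cat("Height (um):\n"); print(x$height_um)
  print(x$band_stats)
  invisible(x)
}

#' @export
plot.force_volume_fit <- function(x, which = c("height", "modulus"), ...) {
  which <- match.arg(which)
  m <- if (which == "height") x$height_um else x$modulus_pass2_pa / 1e3
  graphics::image(t(m[nrow(m):1, ]), axes = FALSE, useRaster = TRUE,
                  main = if (which == "height") "height (um)"
                         else "apparent modulus (kPa)", ...)
  invisible(x)
}
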