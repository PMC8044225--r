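# Synthetic AFM ground-truth generators: virtual cell, single force curves,
# whole force-volume scans. Everything is seeded and bit-reproducible.

# Evaluate expr with a private RNG stream; global .Random.seed is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Build a virtual cell: spherical-cap topography with a stiffer periphery
#'
#' Constructs the ground-truth height and modulus maps that the force-volume
#' simulator scans. The cell is a spherical cap of basal radius `cell_radius`
#' and apex height `max_height` centred in the grid; outside the cap the height
#' is exactly 0 (bare substrate). The modulus is `e_cell` wherever the cell is
#' at least 2 um tall and `e_cell * e_periphery_factor` in the thin peripheral
#' band (0 < height < 2 um), mimicking the flat lamellar region where cortical
#' actin dominates the measured stiffness.
#'
#' @param shape Integer vector `c(nrow, ncol)` of the scan grid.
#' @param cell_radius Basal radius of the cap, um.
#' @param max_height Apex height of the cap, um.
#' @param e_cell True modulus of the tall cell body, Pa.
#' @param e_periphery_factor Multiplier applied to `e_cell` where height
#'   < 2 um (dimensionless).
#' @param pixel_size Scan pixel size, um.
#' @param substrate_modulus Modulus assigned to bare-substrate pixels, Pa.
#'   Should be effectively rigid (>= 1 MPa).
#' @param seed Integer seed recorded with the object (the construction itself
#'   is deterministic).
#' @return An object of class `virtual_cell` with elements `height_map` (um),
#'   `modulus_map` (Pa), `substrate_modulus`, `pixel_size`, `seed`.
#' @examples
#' vc <- make_virtual_cell(c(16, 16), cell_radius = 6, max_height = 4,
#'                         e_cell = 1e4, e_periphery_factor = 1.6,
#'                         pixel_size = 1)
#' range(vc$height_map)
#' @export
make_virtual_cell <- function(shape, cell_radius, max_height, e_cell,
                              e_periphery_factor = 1, pixel_size = 1,
                              substrate_modulus = 1e6, seed = 1L) {
  if (length(shape) != 2 || any(shape < 2))
    stop("'shape' must be c(nrow, ncol) with both >= 2", call. = FALSE)
  if (max_height <= 0 || cell_radius <= 0 || pixel_size <= 0 || e_cell <= 0)
    stop("dimensions and moduli must be positive", call. = FALSE)
  nr <- shape[1]; nc <- shape[2]
  half_extent <- min(nr, nc) * pixel_size / 2
  if (cell_radius >= half_extent)
    stop("cell does not fit in the grid at this pixel size", call. = FALSE)
  # pixel centres in um, origin at grid centre
  rows <- (seq_len(nr) - (nr + 1) / 2) * pixel_size
  cols <- (seq_len(nc) - (nc + 1) / 2) * pixel_size
  r <- sqrt(outer(rows^2, cols^2, `+`))
  # sphere through the cap rim: radius Rs = (a^2 + H^2) / (2H)
  rs <- (cell_radius^2 + max_height^2) / (2 * max_height)
  h <- matrix(0, nr, nc)
  inside <- r <= cell_radius
  h[inside] <- sqrt(pmax(rs^2 - r[inside]^2, 0)) - (rs - max_height)
  h[h < 0] <- 0
  e <- matrix(substrate_modulus, nr, nc)
  e[h > 0] <- e_cell
  e[h > 0 & h < 2] <- e_cell * e_periphery_factor
  structure(
    list(height_map = h, modulus_map = e,
         substrate_modulus = substrate_modulus,
         pixel_size = pixel_size, seed = as.integer(seed)),
    class = "virtual_cell")
}

#' @export
print.virtual_cell <- function(x, ...) {
  cat(sprintf("virtual cell: %d x %d px (%.1f um/px), apex %.2f um, %d cell px\n",
              nrow(x$height_map), ncol(x$height_map), x$pixel_size,
              max(x$height_map), sum(x$height_map > 0)))
  invisible(x)
}

# spring constant in pN/nm (1 N/m = 1000 pN/nm)
spring_pn_nm <- function(probe) probe$spring_constant * 1000

# Solve measured force at piezo position z (> z0): F = A f(chi) delta^{3/2},
# delta = (z - z0) - F/k. g(F) is strictly decreasing; vectorised bisection.
solve_contact_force <- function(z, z0, e_pa, probe, h_um) {
  k <- spring_pn_nm(probe)
  dz <- z - z0
  f <- rep(0, length(z))
  on <- dz > 0
  if (!any(on)) return(f)
  lo <- rep(0, sum(on)); hi <- k * dz[on]
  model <- function(force) {
    delta <- pmax(dz[on] - force / k, 0)
    hertz_force(delta, e_pa, probe, h_um)
  }
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    below <- model(mid) > mid       # root above mid
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  f[on] <- (lo + hi) / 2
  f
}

#' Simulate one AFM approach force curve
#'
#' Forward model of a force-volume approach segment: a linear virtual-
#' deflection baseline before contact, then Hertzian contact with the
#' finite-thickness (bottom-effect) correction, sampled in piezo displacement
#' until the trigger force is reached. The cantilever deflection feedback is
#' honoured: indentation is \eqn{\delta = (z - z_0) - F/k}, solved implicitly
#' per sample by bisection. Gaussian force noise is added last.
#'
#' @param e_true True sample modulus, Pa.
#' @param h Sample thickness, um; `Inf` for a half-space / bare substrate.
#' @param probe A [probe_params()] object.
#' @param baseline_slope Virtual-deflection slope, pN/nm (applied over the
#'   whole trace).
#' @param noise_sd Gaussian force noise SD, pN (>= 0).
#' @param n_points Samples per curve (>= 16).
#' @param seed Integer seed.
#' @param z0 Contact point in the piezo frame, nm. Defaults to placing the
#'   pre-contact segment at 40% of the sampled range.
#' @param pre_contact_fraction Fraction of samples before contact.
#' @param pixel Optional `c(row, col)` label.
#' @return A `force_curve`: list with `z` (nm, increasing toward the sample),
#'   `force` (pN), `probe`, `pixel`, and a `truth` record (z0, e_true, h_um,
#'   baseline_slope, seed).
#' @examples
#' fc <- simulate_force_curve(1e4, Inf, probe_params(), 0, 0, 256, seed = 1)
#' max(fc$force)  # ~ trigger force
#' @export
simulate_force_curve <- function(e_true, h, probe = probe_params(),
                                 baseline_slope = 0, noise_sd = 10,
                                 n_points = 512, seed = 1L, z0 = NULL,
                                 pre_contact_fraction = 0.4, pixel = NULL) {
  stopifnot(inherits(probe, "probe_params"))
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (n_points < 16) stop("'n_points' must be >= 16", call. = FALSE)
  if (!(h > 0)) stop("'h' must be positive (use Inf for substrate)", call. = FALSE)
  if (e_true <= 0) stop("'e_true' must be positive", call. = FALSE)
  k <- spring_pn_nm(probe)
  delta_trig <- invert_hertz_force(probe$trigger_force, e_true, probe, h)
  contact_len <- delta_trig + probe$trigger_force / k   # z span in contact
  pre_len <- contact_len * pre_contact_fraction / (1 - pre_contact_fraction)
  pre_len <- max(pre_len, 20)   # never less than 20 nm of baseline
  if (is.null(z0)) z0 <- pre_len
  z <- seq(z0 - pre_len, z0 + contact_len, length.out = n_points)
  f_contact <- solve_contact_force(z, z0, e_true, probe, h)
  f <- f_contact + baseline_slope * (z - z[1])
  if (noise_sd > 0)
    f <- f + with_seed(seed, stats::rnorm(n_points, 0, noise_sd))
  structure(
    list(z = z, force = f, probe = probe, pixel = pixel,
         truth = list(z0 = z0, e_true = e_true, h_um = h,
                      baseline_slope = baseline_slope,
                      seed = as.integer(seed))),
    class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("force curve: %d samples, z [%.1f, %.1f] nm, Fmax %.1f pN\n",
              length(x$z), min(x$z), max(x$z), max(x$force)))
  invisible(x)
}

#' @export
plot.force_curve <- function(x, ...) {
  graphics::plot(x$z, x$force, type = "l", xlab = "piezo z (nm)",
                 ylab = "force (pN)", ...)
  invisible(x)
}

#' Simulate a force-volume scan of a virtual cell
#'
#' One approach curve per pixel. Cell pixels use the true local modulus and
#' thickness from the [make_virtual_cell()] maps; bare-substrate pixels are
#' simulated as a rigid half-space at `substrate_modulus`. Contact points are
#' laid out in a common piezo frame, \eqn{z_0 = z_{offset} - h + tilt}, so the
#' scan carries real topography (taller sample contacts earlier) and an
#' optional stage tilt plane for testing the flattening step.
#'
#' @param cell A `virtual_cell`.
#' @param probe A [probe_params()] object.
#' @param noise_sd Force noise SD, pN.
#' @param seed Integer seed; per-pixel streams are derived from it.
#' @param baseline_slope Virtual-deflection slope, pN/nm.
#' @param tilt Stage tilt `c(per_row, per_col)` in nm/pixel added to every
#'   contact point.
#' @param n_points Samples per curve.
#' @param z_offset Piezo frame origin for substrate contact, nm.
#' @return A list with `map` (a `force_volume` of curves plus `pixel_size`)
#'   and `truth` (a `synthetic_truth` of kind `"force_volume"` carrying the
#'   true height, modulus and z0 maps).
#' @export
simulate_force_volume <- function(cell, probe = probe_params(), noise_sd = 10,
                                  seed = 1L, baseline_slope = 0.02,
                                  tilt = c(0, 0), n_points = 256,
                                  z_offset = 8000) {
  stopifnot(inherits(cell, "virtual_cell"))
  nr <- nrow(cell$height_map); nc <- ncol(cell$height_map)
  h_nm <- cell$height_map * 1e3
  z0_map <- z_offset - h_nm +
    outer(seq_len(nr), seq_len(nc),
          function(i, j) tilt[1] * i + tilt[2] * j)
  seeds <- with_seed(seed, sample.int(2^31 - 2, nr * nc))
  curves <- vector("list", nr * nc)
  dim(curves) <- c(nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      on_cell <- cell$height_map[i, j] > 0
      curves[[i, j]] <- simulate_force_curve(
        e_true = if (on_cell) cell$modulus_map[i, j] else cell$substrate_modulus,
        h = if (on_cell) cell$height_map[i, j] else Inf,
        probe = probe, baseline_slope = baseline_slope,
        noise_sd = noise_sd, n_points = n_points,
        seed = seeds[(j - 1) * nr + i], z0 = z0_map[i, j],
        pixel = c(i, j))
    }
  }
  map <- structure(list(curves = curves, pixel_size = cell$pixel_size,
                        probe = probe),
                   class = "force_volume")
  truth <- structure(
    list(kind = "force_volume",
         payload = list(height_map = cell$height_map,
                        modulus_map = cell$modulus_map,
                        z0_map = z0_map,
                        substrate_mask = cell$height_map == 0),
         seed = as.integer(seed)),
    class = "synthetic_truth")
  list(map = map, truth = truth)
}

#' @export
print.force_volume <- function(x, ...) {
  d <- dim(x$curves)
  cat(sprintf("force volume: %d x %d curves, %.2f um/px\n",
              d[1], d[2], x$pixel_size))
  invisible(x)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic truth [", x$kind, "], seed ", x$seed, "\n", sep = "")
  invisible(x)
}
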