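#' Cantilever probe parameters
#'
#' Bundles the physical parameters of the AFM probe used both by the forward
#' force simulator and by the Hertz fitting routines. Defaults reproduce a
#' sharp paraboloidal-apex cantilever commonly used for fast force-volume
#' mapping of live cells: 35 nm tip radius, 0.068 N/m spring constant,
#' incompressible sample (Poisson ratio 0.5) and a 400 pN trigger force.
#'
#' @param tip_radius Tip apex radius in nm. Must be positive.
#' @param spring_constant Cantilever spring constant in N/m. Must be positive.
#' @param poisson_ratio Sample Poisson ratio (dimensionless, in [0, 0.5]).
#' @param trigger_force Force setpoint terminating each approach curve, in pN.
#' @param velocity Probe approach velocity in um/s. Metadata only; the
#'   quasi-static Hertz model does not use it.
#'
#' @return An object of class `probe_params`.
#' @examples
#' p <- probe_params()
#' p$tip_radius
#' @export
probe_params <- function(tip_radius = 35, spring_constant = 0.068,
                         poisson_ratio = 0.5, trigger_force = 400,
                         velocity = 100) {
  if (!is.numeric(tip_radius) || tip_radius <= 0)
    stop("'tip_radius' must be a positive length in nm", call. = FALSE)
  if (!is.numeric(spring_constant) || spring_constant <= 0)
    stop("'spring_constant' must be a positive stiffness in N/m", call. = FALSE)
  if (!is.numeric(poisson_ratio) || poisson_ratio < 0 ||
      poisson_ratio > 0.5 + 1e-12)
    stop("'poisson_ratio' must lie in [0, 0.5]", call. = FALSE)
  if (!is.numeric(trigger_force) || trigger_force <= 0)
    stop("'trigger_force' must be a positive force in pN", call. = FALSE)
  structure(
    list(tip_radius = as.numeric(tip_radius),
         spring_constant = as.numeric(spring_constant),
         poisson_ratio = as.numeric(poisson_ratio),
         trigger_force = as.numeric(trigger_force),
         velocity = as.numeric(velocity)),
    class = "probe_params")
}

#' @export
print.probe_params <- function(x, ...) {
  cat("AFM probe: R =", x$tip_radius, "nm, k =", x$spring_constant,
      "N/m, nu =", x$poisson_ratio, ", trigger =", x$trigger_force, "pN\n")
  invisible(x)
}

#' Bottom-effect correction factor for a thin bonded sample
#'
#' Multiplicative correction to the Hertz force for a paraboloidal tip
#' indenting a thin elastic layer bonded to a rigid substrate:
#' \deqn{f(\chi) = 1 + 1.133\chi + 1.283\chi^2 + 0.769\chi^3 + 0.0975\chi^4}
#' with \eqn{\chi = \sqrt{R\delta}/h}, where R is the tip radius, \eqn{\delta}
#' the indentation and h the local sample thickness. `f(0) = 1` recovers the
#' semi-infinite half-space (plain Hertz) limit; f is strictly increasing, so
#' thin samples always appear stiffer than their true modulus when the
#' correction is ignored.
#'
#' @param chi Dimensionless ratio \eqn{\sqrt{R\delta}/h}; must be >= 0.
#'   Vectorised.
#' @return Correction factor(s) >= 1.
#' @examples
#' bottom_effect_factor(0)  # exactly 1
#' bottom_effect_factor(1)  # 4.2825
#' @export
bottom_effect_factor <- function(chi) {
  if (!is.numeric(chi)) stop("'chi' must be numeric", call. = FALSE)
  if (any(chi < 0, na.rm = TRUE))
    stop("'chi' must be non-negative", call. = FALSE)
  1 + 1.133 * chi + 1.283 * chi^2 + 0.769 * chi^3 + 0.0975 * chi^4
}

# Hertz prefactor in pN / nm^{3/2}: F = A * delta^{3/2} with delta in nm.
# E in Pa, R in nm; 1e-6 converts SI (N, m) to (pN, nm).
hertz_prefactor <- function(e_pa, tip_radius_nm, poisson_ratio) {
  (4 / 3) * e_pa / (1 - poisson_ratio^2) * sqrt(tip_radius_nm) * 1e-6
}

#' Forward Hertz force with finite-thickness correction
#'
#' Evaluates the contact force of a paraboloidal tip indenting an elastic
#' sample of thickness `h_um` bonded to a rigid substrate,
#' \deqn{F(\delta) = \frac{4}{3}\frac{E}{1-\nu^2}\sqrt{R}\,\delta^{3/2}
#'   f(\sqrt{R\delta}/h),}
#' in the units of this package's public API (pN, nm, Pa, um).
#'
#' @param delta Indentation depth(s), nm (>= 0).
#' @param e_pa Elastic modulus, Pa.
#' @param probe A [probe_params()] object.
#' @param h_um Sample thickness in um; `Inf` gives the plain Hertz half-space.
#' @return Force in pN, same length as `delta`.
#' @examples
#' hertz_force(100, 10e3, probe_params())  # ~105 pN
#' @export
hertz_force <- function(delta, e_pa, probe, h_um = Inf) {
  stopifnot(inherits(probe, "probe_params"))
  if (any(delta < 0, na.rm = TRUE))
    stop("'delta' must be non-negative", call. = FALSE)
  a <- hertz_prefactor(e_pa, probe$tip_radius, probe$poisson_ratio)
  chi <- if (is.finite(h_um)) sqrt(probe$tip_radius * delta) / (h_um * 1e3)
         else rep(0, length(delta))
  a * delta^1.5 * bottom_effect_factor(chi)
}

# Invert F(delta) = target for delta (nm) by bisection; monotone in delta.
invert_hertz_force <- function(target_pn, e_pa, probe, h_um = Inf,
                               rtol = 1e-12) {
  lo <- 0
  hi <- 1
  while (hertz_force(hi, e_pa, probe, h_um) < target_pn) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (hertz_force(mid, e_pa, probe, h_um) < target_pn) lo <- mid else hi <- mid
    if ((hi - lo) <= rtol * max(hi, 1)) break
  }
  (lo + hi) / 2
}
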