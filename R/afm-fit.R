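# Per-curve AFM analysis: virtual-deflection baseline removal and the
# two-pass Hertz fit (linearized half-space fit, then nonlinear refit with
# the finite-thickness correction at known local height).

#' Remove the virtual-deflection baseline from a force curve
#'
#' Fits a straight line to the pre-contact portion of the approach trace (the
#' first `baseline_fraction` of samples) by least squares and subtracts it
#' from the whole force trace. The optical-lever readout of AFM instruments
#' carries a spurious linear trend ("virtual deflection") that must be removed
#' before any contact-mechanics fit.
#'
#' A curve is flagged `no_baseline` when the baseline window is not a credible
#' force-free segment: its residual SD exceeds `max_baseline_sd`, or the
#' corrected force inside the window rises above 3x that SD (the window
#' overlaps contact).
#'
#' @param curve A `force_curve`.
#' @param baseline_fraction Fraction of leading samples treated as
#'   pre-contact; default 0.3.
#' @param max_baseline_sd Largest residual SD (pN) for which the baseline is
#'   considered identifiable; default 25 pN.
#' @return The corrected `force_curve` with a `baseline` element:
#'   `slope` (pN/nm), `intercept` (pN), `sd` (pN, residual SD), `n` (window
#'   size), `status` (`"ok"` or `"no_baseline"`).
#' @export
correct_virtual_deflection <- function(curve, baseline_fraction = 0.3,
                                       max_baseline_sd = 25) {
  stopifnot(inherits(curve, "force_curve"))
  n <- length(curve$z)
  if (stats::var(curve$z) == 0)
    stop("degenerate curve: piezo displacement has zero variance", call. = FALSE)
  nb <- max(8L, floor(n * baseline_fraction))
  idx <- seq_len(min(nb, n))
  fit <- stats::lm.fit(cbind(1, curve$z[idx]), curve$force[idx])
  slope <- fit$coefficients[2]
  intercept <- fit$coefficients[1]
  sd_res <- sqrt(sum(fit$residuals^2) / max(length(idx) - 2, 1))
  corrected <- curve$force - (intercept + slope * curve$z)
  status <- "ok"
  contact_thresh <- max(3 * sd_res, 1e-6)
  if (sd_res > max_baseline_sd) status <- "no_baseline"
  # contact inside the window: a sustained (not single-sample) excursion
  if (!is.na(first_sustained_crossing(corrected[idx], contact_thresh)))
    status <- "no_baseline"
  out <- curve
  out$force <- corrected
  out$baseline <- list(slope = unname(slope), intercept = unname(intercept),
                       sd = sd_res, n = length(idx), status = status)
  out
}

# Assemble a hertz_fit result object (also used for failed fits).
new_hertz_fit <- function(status, method, curve = NULL, z0 = NA_real_,
                          e = NA_real_, rmse = NA_real_, n_fit = 0L,
                          h_um = Inf, fit_idx = integer(0)) {
  structure(
    list(status = status, method = method,
         contact_point_z0 = z0, apparent_modulus = e,
         baseline_slope = if (!is.null(curve$baseline)) curve$baseline$slope else NA_real_,
         baseline_sd = if (!is.null(curve$baseline)) curve$baseline$sd else NA_real_,
         fit_rmse = rmse, n_fit_points = n_fit, h_um = h_um,
         probe = curve$probe, curve = curve, fit_idx = fit_idx),
    class = "hertz_fit")
}

# First index where force stays above `thresh` for `run` consecutive samples.
first_sustained_crossing <- function(force, thresh, run = 4L) {
  above <- force > thresh
  if (length(above) < run) return(NA_integer_)
  cs <- cumsum(above)
  win <- cs - c(rep(0, run), utils::head(cs, -run))
  hit <- which(win == run)
  if (!length(hit)) return(NA_integer_)
  hit[1] - run + 1L
}

#' First-pass Hertz fit by power-law linearization
#'
#' Inverts the Hertz power law on the contact branch and fits a straight
#' line: with tip-sample separation \eqn{s = z - F/k}, the transform
#' \eqn{y = F^{2/3}} is linear in s for a paraboloidal indenter,
#' \eqn{y = a (s - s_0)}. The slope and x-intercept give the apparent modulus
#' \eqn{E = \frac{3}{4} (1-\nu^2)\, a^{3/2} / \sqrt{R}} and the contact point
#' \eqn{z_0 = s_0}. The contact branch is identified by the first sustained
#' crossing (4 consecutive samples) of a force threshold at 3x the baseline
#' noise SD, then refined once using the fitted intercept; points are
#' restricted to indentations <= `max_indentation` and the line is fitted by
#' iteratively reweighted least squares (Tukey bisquare).
#'
#' @param curve A baseline-corrected `force_curve` (see
#'   [correct_virtual_deflection()]).
#' @param max_indentation Largest indentation depth used in the fit, nm.
#' @return An object of class `hertz_fit`; see [coef.hertz_fit()]. `status`
#'   is `"no_contact"` when fewer than 8 points lie above threshold or the
#'   fitted slope is not positive.
#' @seealso [fit_bottom_effect()] for the thickness-corrected second pass.
#' @export
fit_hertz_linearized <- function(curve, max_indentation = 800) {
  stopifnot(inherits(curve, "force_curve"))
  if (is.null(curve$baseline))
    curve <- correct_virtual_deflection(curve)
  if (curve$baseline$status != "ok")
    return(new_hertz_fit("no_baseline", "linearized", curve))
  k <- spring_pn_nm(curve$probe)
  s <- curve$z - curve$force / k
  thresh <- max(3 * curve$baseline$sd, 1e-6)
  start <- first_sustained_crossing(curve$force, thresh)
  if (is.na(start))
    return(new_hertz_fit("no_contact", "linearized", curve))

  fit_branch <- function(idx) {
    y <- curve$force[idx]^(2 / 3)
    w <- rep(1, length(idx))
    a <- s0 <- NA_real_
    for (it in 1:3) {
      fit <- stats::lm.wfit(cbind(1, s[idx]), y, w)
      a <- fit$coefficients[2]
      if (!is.finite(a) || a <= 0) return(NULL)
      s0 <- -fit$coefficients[1] / a
      r <- fit$residuals
      scale <- stats::median(abs(r)) / 0.6745
      if (scale <= 0) break                    # noiseless: OLS is exact
      u <- r / (4.685 * scale)
      w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    }
    list(a = unname(a), s0 = unname(s0))
  }

  idx <- which(seq_along(s) >= start & curve$force > thresh)
  if (length(idx) < 8)
    return(new_hertz_fit("no_contact", "linearized", curve))
  pass <- fit_branch(idx)
  if (is.null(pass))
    return(new_hertz_fit("no_contact", "linearized", curve))
  # one refinement: re-select the branch from the fitted contact point and
  # enforce the indentation cap
  delta <- s - pass$s0
  idx <- which(delta > 0 & curve$force > thresh & delta <= max_indentation)
  if (length(idx) < 8)
    return(new_hertz_fit("no_contact", "linearized", curve))
  pass <- fit_branch(idx)
  if (is.null(pass))
    return(new_hertz_fit("no_contact", "linearized", curve))

  probe <- curve$probe
  a_big <- pass$a^(3 / 2)   # Hertz prefactor, pN / nm^{3/2}
  e_pa <- 0.75 * (1 - probe$poisson_ratio^2) * a_big /
    sqrt(probe$tip_radius) * 1e6
  pred <- a_big * pmax(s[idx] - pass$s0, 0)^1.5
  rmse <- sqrt(mean((curve$force[idx] - pred)^2))
  new_hertz_fit("ok", "linearized", curve, z0 = pass$s0, e = e_pa,
                rmse = rmse, n_fit = length(idx), h_um = Inf, fit_idx = idx)
}

#' Second-pass Hertz fit with the bottom-effect (finite thickness) correction
#'
#' Nonlinear least-squares refit of the contact branch with the thin-sample
#' model \eqn{F(\delta) = \frac{4}{3}\frac{E}{1-\nu^2}\sqrt{R}\,\delta^{3/2}
#' f(\sqrt{R\delta}/h)} at fixed, known local thickness h (from the flattened
#' topography). The modulus is free (optimised on a log scale); the contact
#' point may move within +/- `z0_window` nm of the first-pass value, which
#' prevents the degenerate trade-off between E and z0 on shallow curves. If
#' the optimiser fails, the first-pass result is kept and flagged.
#'
#' @param curve A baseline-corrected `force_curve`.
#' @param h Local sample thickness, um (`Inf` allowed: plain Hertz limit).
#' @param first_pass A `hertz_fit` from [fit_hertz_linearized()] providing
#'   the initial E and z0. Computed on the fly when missing.
#' @param max_indentation Largest indentation used, nm.
#' @param z0_window Allowed contact-point excursion from the first pass, nm.
#'   Use 0 to refit the modulus only.
#' @return A `hertz_fit` with `method = "bottom_effect"`. `status` is
#'   `"fallback"` when the optimiser did not converge and the first-pass
#'   modulus was kept.
#' @export
fit_bottom_effect <- function(curve, h, first_pass = NULL,
                              max_indentation = 800, z0_window = 20) {
  stopifnot(inherits(curve, "force_curve"))
  if (!(h > 0)) stop("'h' must be positive (um)", call. = FALSE)
  if (is.null(first_pass)) first_pass <- fit_hertz_linearized(curve, max_indentation)
  if (first_pass$status != "ok") return(first_pass)
  probe <- curve$probe
  k <- spring_pn_nm(probe)
  s <- curve$z - curve$force / k
  z0_init <- first_pass$contact_point_z0
  thresh <- max(3 * curve$baseline$sd, 1e-6)
  delta0 <- s - z0_init
  idx <- which(delta0 > 0 & curve$force > thresh & delta0 <= max_indentation)
  if (length(idx) < 8) return(first_pass)
  h_nm <- h * 1e3
  model <- function(log_e, z0) {
    delta <- pmax(s[idx] - z0, 0)
    chi <- if (is.finite(h_nm)) sqrt(probe$tip_radius * delta) / h_nm else 0
    hertz_prefactor(exp(log_e), probe$tip_radius, probe$poisson_ratio) *
      delta^1.5 * bottom_effect_factor(chi)
  }
  resid_fn <- function(par) model(par[1], par[2]) - curve$force[idx]
  start <- c(log(first_pass$apparent_modulus), z0_init)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start, fn = resid_fn,
      lower = c(log(1), z0_init - z0_window),
      upper = c(log(1e9), z0_init + z0_window),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) {
    out <- first_pass
    out$status <- "fallback"
    return(out)
  }
  e_pa <- exp(fit$par[1]); z0 <- fit$par[2]
  rmse <- sqrt(mean(fit$fvec^2))
  new_hertz_fit("ok", "bottom_effect", curve, z0 = z0, e = e_pa,
                rmse = rmse, n_fit = length(idx), h_um = h, fit_idx = idx)
}

#' @export
print.hertz_fit <- function(x, digits = 4, ...) {
  cat("Hertz fit (", x$method, "), status: ", x$status, "\n", sep = "")
  if (x$status %in% c("ok", "fallback")) {
    cat(sprintf("  apparent modulus: %s kPa\n",
                format(x$apparent_modulus / 1e3, digits = digits)))
    cat(sprintf("  contact point z0: %s nm\n",
                format(x$contact_point_z0, digits = digits)))
    if (is.finite(x$h_um))
      cat(sprintf("  sample thickness: %s um (bottom-effect corrected)\n",
                  format(x$h_um, digits = digits)))
    cat(sprintf("  fit RMSE: %s pN over %d points\n",
                format(x$fit_rmse, digits = digits), x$n_fit_points))
  }
  invisible(x)
}

#' Extract fitted Hertz parameters
#'
#' @param object A `hertz_fit`.
#' @param ... Unused.
#' @return Named vector `c(apparent_modulus_pa, contact_point_z0_nm)`.
#' @export
coef.hertz_fit <- function(object, ...) {
  c(apparent_modulus_pa = object$apparent_modulus,
    contact_point_z0_nm = object$contact_point_z0)
}

#' Predict force from a fitted Hertz model
#'
#' @param object A `hertz_fit`.
#' @param delta Indentation depths (nm) at which to evaluate the fitted
#'   force law; defaults to the indentations used in the fit.
#' @param ... Unused.
#' @return Predicted force, pN.
#' @export
predict.hertz_fit <- function(object, delta = NULL, ...) {
  if (!object$status %in% c("ok", "fallback"))
    stop("cannot predict from a failed fit", call. = FALSE)
  if (is.null(delta)) {
    k <- spring_pn_nm(object$probe)
    s <- object$curve$z - object$curve$force / k
    delta <- pmax(s[object$fit_idx] - object$contact_point_z0, 0)
  }
  hertz_force(delta, object$apparent_modulus, object$probe, object$h_um)
}

#' @export
fitted.hertz_fit <- function(object, ...) predict(object)

#' @export
residuals.hertz_fit <- function(object, ...) {
  object$curve$force[object$fit_idx] - fitted(object)
}

#' @export
plot.hertz_fit <- function(x, ...) {
  graphics::plot(x$curve$z, x$curve$force, type = "l", col = "grey40",
                 xlab = "piezo z (nm)", ylab = "force (pN)", ...)
  if (x$status %in% c("ok", "fallback")) {
    graphics::points(x$curve$z[x$fit_idx], fitted(x), col = "red3",
                     pch = ".", cex = 2)
    graphics::abline(v = x$contact_point_z0, lty = 2)
  }
  invisible(x)
}
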