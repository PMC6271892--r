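## Slit (line-beam) smearing and its inverse, plus the reduction helpers a
## Kratky-camera dataset needs: polynomial smoothing and absolute scaling.

#' Slit beam-length profile
#'
#' The weighting kernel W(t) describing the beam length of a slit-collimated
#' (line-beam) camera.  The smeared intensity is
#' \eqn{\tilde I(q) = 2\int_0^{t_{max}} W(t)\, I(\sqrt{q^2+t^2})\, dt},
#' with W normalized so that \eqn{\int_0^{t_{max}} W\,dt = 1/2} (symmetric
#' kernel, half-line stored).  The default is a trapezoid: flat to `t1`,
#' falling linearly to `t_max` — the typical block-collimation shape.  A
#' `"delta"` profile represents pinhole (no-smearing) geometry.
#'
#' @param type `"trapezoid"` or `"delta"`.
#' @param t1 Plateau end, 1/Angstrom (trapezoid only).
#' @param t_max Kernel support end, 1/Angstrom.
#' @param n Number of tabulation points.
#' @return An object of class `slit_profile` with fields `t`, `w`.
#' @export
slit_profile <- function(type = c("trapezoid", "delta"), t1 = 0.05,
                         t_max = 0.2, n = 33L) {
  type <- match.arg(type)
  if (type == "delta")
    return(structure(list(type = "delta", t = 0, w = Inf, t_max = 0),
                     class = "slit_profile"))
  if (!(t1 >= 0 && t_max > t1))
    stop_micello("invariant_violation", "need 0 <= t1 < t_max")
  t <- seq(0, t_max, length.out = n)
  w <- ifelse(t <= t1, 1, (t_max - t) / (t_max - t1))
  w <- w / (2 * trapz(t, w))  # integral over half-line = 1/2
  structure(list(type = "trapezoid", t = t, w = w, t1 = t1, t_max = t_max),
            class = "slit_profile")
}

#' @export
print.slit_profile <- function(x, ...) {
  if (x$type == "delta") cat("<slit_profile> delta (pinhole)\n")
  else cat(sprintf("<slit_profile> trapezoid, t1 = %.3g, t_max = %.3g 1/A\n",
                   x$t1, x$t_max))
  invisible(x)
}

## Interpolator for I(q) with a power-law tail fitted to the last decade of
## (positive) points, used to close the smearing integral beyond the
## measured range.
curve_interpolator <- function(curve) {
  q <- curve$q; I <- curve$intensity
  qmax <- max(q)
  tailidx <- which(q >= qmax / 10 & I > 0)
  if (length(tailidx) >= 3L) {
    fit <- lm(log(I[tailidx]) ~ log(q[tailidx]))
    tail_a <- exp(coef(fit)[[1L]]); tail_b <- coef(fit)[[2L]]
  } else {  # flat continuation as a fallback for short/nonpositive tails
    tail_a <- I[length(I)]; tail_b <- 0
  }
  function(qq) {
    out <- approx(q, I, xout = pmin(qq, qmax))$y
    beyond <- qq > qmax
    if (any(beyond)) out[beyond] <- tail_a * qq[beyond]^tail_b
    out
  }
}

#' Apply slit smearing to a curve
#'
#' Forward operator \eqn{\tilde I(q) = 2\int_0^{t_{max}} W(t)
#' I(\sqrt{q^2+t^2}) dt} (trapezoid quadrature over the tabulated kernel).
#' Beyond the measured q range the curve is continued as a power law fitted
#' to its last decade of points.
#'
#' @param curve An unsmeared [scattering_curve()].
#' @param profile A [slit_profile()].
#' @return A [scattering_curve()] flagged smeared.
#' @export
slit_smear <- function(curve, profile) {
  stopifnot(inherits(curve, "scattering_curve"), inherits(profile, "slit_profile"))
  if (curve$smeared)
    stop_micello("state_error", "curve is already slit-smeared")
  out <- curve
  if (profile$type != "delta") {
    interp <- curve_interpolator(curve)
    out$intensity <- vapply(curve$q, function(q) {
      2 * trapz(profile$t, profile$w * interp(sqrt(q^2 + profile$t^2)))
    }, numeric(1L))
  }
  out$smeared <- TRUE
  out
}

#' Iteratively desmear a slit-smeared curve
#'
#' Multiplicative (Lake-type) iteration
#' \eqn{I^{(k+1)} = I^{(k)} \cdot \tilde I_{obs} / S[I^{(k)}]}, where S is
#' [slit_smear()], initialized at the observed curve and stopped when the
#' maximum relative change drops below `tol` or after `max_iter`
#' iterations.  Non-positive observed intensities are clipped to a small
#' positive floor (with a warning) since the scheme is multiplicative.
#'
#' Points with \eqn{q > \sqrt{q_{max}^2 - t_{max}^2}} have smearing
#' integrals that reach beyond the measured range and rest on the
#' extrapolated tail; they accumulate closure error under iteration and are
#' dropped by default (`trim_tail = TRUE`).
#'
#' @param curve A smeared [scattering_curve()].
#' @param profile The [slit_profile()] that produced the smearing.
#' @param max_iter Maximum iterations.
#' @param tol Relative-change stopping tolerance.
#' @param trim_tail Drop the extrapolation-dependent high-q points?
#' @return An unsmeared [scattering_curve()]; `meta$desmear` records the
#'   iteration count and final change, and a warning is raised on
#'   non-convergence (best iterate returned).
#' @export
desmear <- function(curve, profile, max_iter = 30L, tol = 1e-4,
                    trim_tail = TRUE) {
  stopifnot(inherits(curve, "scattering_curve"), inherits(profile, "slit_profile"))
  if (!curve$smeared)
    stop_micello("state_error", "curve is not flagged smeared")
  obs <- curve$intensity
  if (any(obs <= 0)) {
    floorv <- 1e-6 * max(obs)
    warning(sprintf("%d non-positive intensities clipped to %.3g before desmearing",
                    sum(obs <= 0), floorv), call. = FALSE)
    obs[obs <= 0] <- floorv
  }
  if (profile$type == "delta") {
    out <- curve; out$intensity <- obs; out$smeared <- FALSE
    out$meta$desmear <- list(iterations = 1L, rel_change = 0)
    return(out)
  }
  Ik <- obs
  rel <- Inf
  iter <- 0L
  while (iter < max_iter && rel >= tol) {
    iter <- iter + 1L
    trial <- curve; trial$intensity <- Ik; trial$smeared <- FALSE
    SIk <- slit_smear(trial, profile)$intensity
    Inew <- Ik * obs / pmax(SIk, 1e-12 * max(SIk))
    rel <- max(abs(Inew - Ik) / pmax(abs(Ik), 1e-12 * max(abs(Ik))))
    Ik <- Inew
  }
  if (rel >= tol)
    warning(sprintf("desmear did not converge in %d iterations (last relative change %.3g); best iterate returned",
                    max_iter, rel), call. = FALSE)
  out <- curve
  out$intensity <- Ik
  out$smeared <- FALSE
  out$meta$desmear <- list(iterations = iter, rel_change = rel)
  if (trim_tail) {
    qcut <- sqrt(max(out$q)^2 - profile$t_max^2)
    keep <- out$q <= qcut
    out <- scattering_curve(out$q[keep], out$intensity[keep],
                            sigma = out$sigma[keep], smeared = FALSE,
                            meta = out$meta)
  }
  out
}

#' Cubic moving-polynomial smoothing
#'
#' Replaces each point by the value at its q of a third-degree polynomial
#' least-squares fitted over a window of adjacent points
#' (Savitzky-Golay-equivalent on a uniform grid, but fitted in q so uneven
#' grids are handled); at the curve ends the window keeps its width and
#' becomes one-sided (shifted inward), so a window equal to the curve
#' length is a single global cubic fit.
#'
#' @param curve A [scattering_curve()].
#' @param window Odd window length, at least 5, at most the curve length.
#' @return The smoothed [scattering_curve()].
#' @export
smooth_curve <- function(curve, window = 11L) {
  stopifnot(inherits(curve, "scattering_curve"))
  n <- length(curve$q)
  if (window %% 2L != 1L || window < 5L)
    stop_micello("invariant_violation", "window must be odd and >= 5")
  if (window > n)
    stop_micello("invariant_violation", "window (%d) exceeds curve length (%d)",
                 window, n)
  h <- (window - 1L) %/% 2L
  out <- curve
  q <- curve$q; I <- curve$intensity
  out$intensity <- vapply(seq_len(n), function(i) {
    lo <- min(max(1L, i - h), n - window + 1L)
    idx <- lo:(lo + window - 1L)
    qi <- q[idx] - q[i]  # center for conditioning
    co <- coef(lm(I[idx] ~ qi + I(qi^2) + I(qi^3)))
    co[[1L]]
  }, numeric(1L))
  out
}

#' Put a curve on absolute scale using the water standard
#'
#' Multiplies the intensity by
#' `water_reference / (transmission * measured_water_level)`, i.e.
#' calibrates against the measured flat scattering level of water and the
#' standard value of water scattering, 1.68e-2 (the conventional unit of
#' this constant is 1/cm; it is sometimes printed as cm^-2).  Applying the
#' calibration twice is an error.
#'
#' @param curve A [scattering_curve()].
#' @param transmission Sample transmission, in (0, 1].
#' @param measured_water_level Measured water scattering level, instrument
#'   units (> 0).
#' @param water_reference Absolute water scattering standard (default
#'   1.68e-2).
#' @return The rescaled curve; `meta$absolute_scale_factor` records the
#'   factor and `meta$absolute_scaled` guards reapplication.
#' @export
absolute_scale <- function(curve, transmission, measured_water_level,
                           water_reference = 1.68e-2) {
  stopifnot(inherits(curve, "scattering_curve"))
  if (isTRUE(curve$meta$absolute_scaled))
    stop_micello("state_error", "curve is already on absolute scale")
  if (!(transmission > 0 && transmission <= 1))
    stop_micello("invariant_violation", "transmission must lie in (0, 1]")
  if (!(measured_water_level > 0))
    stop_micello("scaling_error", "measured water level must be positive")
  if (!(water_reference > 0))
    stop_micello("invariant_violation", "water reference must be positive")
  f <- water_reference / (transmission * measured_water_level)
  out <- curve
  out$intensity <- curve$intensity * f
  if (!is.null(curve$sigma)) out$sigma <- curve$sigma * f
  out$meta$absolute_scaled <- TRUE
  out$meta$absolute_scale_factor <- f
  out
}
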