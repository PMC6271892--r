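## Forward scattering from bead models: the Debye equation, exact pair
## histograms, the sine back-transform and scale/chi comparison.

#' Debye-equation scattering intensity of a bead model
#'
#' Evaluates \eqn{I(q) = \sum_i \sum_j w_i w_j \sin(q r_{ij})/(q r_{ij})}
#' over all bead pairs (self terms contribute \eqn{w_i^2};
#' \eqn{\sin(x)/x \to 1} at \eqn{x = 0}).  The absolute prefactor is
#' arbitrary — model curves are matched to experiment with [scale_to()].
#' Exact but O(n^2) per q point; the inner loop is compiled.
#'
#' @param model A [bead_model()].
#' @param q_grid Positive, strictly increasing q values, 1/Angstrom.
#' @return A [scattering_curve()] (unsmeared).
#' @examples
#' m <- bead_model(rbind(c(0, 0, 0), c(0, 0, 10)))
#' debye_intensity(m, c(0.05, 0.1))
#' @export
debye_intensity <- function(model, q_grid) {
  stopifnot(inherits(model, "bead_model"))
  q_grid <- as.numeric(q_grid)
  if (any(q_grid <= 0))
    stop_micello("invariant_violation", "q_grid must be positive")
  I <- debye_sum_cpp(model$positions, model$weights, q_grid)
  scattering_curve(q = q_grid, intensity = I, smeared = FALSE,
                   meta = list(label = model$label %||% "debye",
                               n_beads = nrow(model$positions)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analytic sphere form factor
#'
#' \eqn{I(q)/I(0) = [3(\sin(qR) - qR\cos(qR))/(qR)^3]^2} for a homogeneous
#' sphere of radius `R`; the analytic oracle against which bead-model
#' scattering is validated.
#'
#' @param R Sphere radius, Angstrom.
#' @param q_grid Positive q values, 1/Angstrom.
#' @param i0 Forward intensity I(0) (default 1).
#' @return A [scattering_curve()].
#' @export
sphere_form_factor <- function(R, q_grid, i0 = 1) {
  if (R <= 0) stop_micello("invariant_violation", "R must be positive")
  x <- as.numeric(q_grid) * R
  amp <- ifelse(x == 0, 1, 3 * (sin(x) - x * cos(x)) / x^3)
  scattering_curve(q = q_grid, intensity = i0 * amp^2,
                   meta = list(label = sprintf("sphere R=%g", R)))
}

#' Closed-form p(r) of a homogeneous sphere
#'
#' \eqn{p(r) \propto r^2 (1 - 3x/2 + x^3/2)} with \eqn{x = r/(2R)}, on
#' `[0, 2R]`; used as an analytic oracle for the IFT and shape extraction.
#'
#' @param R Sphere radius, Angstrom.
#' @param n Number of grid points.
#' @return A [pair_distribution()].
#' @export
sphere_pr <- function(R, n = 201L) {
  r <- seq(0, 2 * R, length.out = n)
  x <- r / (2 * R)
  pair_distribution(r = r, p = r^2 * (1 - 1.5 * x + 0.5 * x^3), dmax = 2 * R)
}

#' Exact pair-distance distribution of a bead model
#'
#' Weighted histogram of all n(n-1)/2 pairwise distances (pair weight
#' \eqn{w_i w_j}) on bins of width `bin_width`; the brute-force oracle for
#' p(r).  `D_max` is the maximum pairwise distance.
#'
#' @param model A [bead_model()] with at least two beads.
#' @param bin_width Bin width in Angstrom.
#' @return A [pair_distribution()] with `r` at bin centers (0 prepended).
#' @export
pr_exact <- function(model, bin_width = 1) {
  stopifnot(inherits(model, "bead_model"))
  if (nrow(model$positions) < 2L)
    stop_micello("degenerate_distribution",
                 "pair distribution undefined for a single bead")
  if (bin_width <= 0)
    stop_micello("invariant_violation", "bin_width must be positive")
  ext <- apply(model$positions, 2L, range)
  upper <- sqrt(sum((ext[2L, ] - ext[1L, ])^2))  # diagonal bounds any pair
  nbins <- max(1L, ceiling(upper / bin_width) + 1L)
  h <- pair_hist_cpp(model$positions, model$weights, bin_width, nbins)
  keep <- seq_len(min(nbins, floor(h$dmax / bin_width) + 1L))
  centers <- (keep - 0.5) * bin_width
  pair_distribution(r = c(0, centers), p = c(0, h$counts[keep]), dmax = h$dmax)
}

#' Sine back-transform of a pair distribution
#'
#' \eqn{I(q) = 4\pi \int_0^{D_{max}} p(r) \sin(qr)/(qr)\, dr} by the
#' trapezoid rule on the stored grid; the inverse companion of the Debye
#' sum, so `back_transform(pr_exact(m), q)` should agree with
#' `debye_intensity(m, q)` up to histogram discretization.
#'
#' @param pr A [pair_distribution()].
#' @param q_grid Positive q values, 1/Angstrom.
#' @return A [scattering_curve()].
#' @export
back_transform <- function(pr, q_grid) {
  stopifnot(inherits(pr, "pair_distribution"))
  q_grid <- as.numeric(q_grid)
  if (any(q_grid <= 0))
    stop_micello("invariant_violation", "q_grid must be positive")
  I <- vapply(q_grid, function(q) 4 * pi * trapz(pr$r, pr$p * sinc(q * pr$r)),
              numeric(1L))
  scattering_curve(q = q_grid, intensity = I, meta = list(label = "back_transform"))
}

#' Scale a model curve onto an experimental curve
#'
#' Finds the least-squares scalar `s` minimizing
#' \eqn{\sum_k [(I_{exp,k} - s I_{th,k})/\sigma_k]^2} (the model first
#' interpolated linearly onto the experimental q grid) and the discrepancy
#' \eqn{\chi = \sqrt{\min / (n - 1)}}.  \eqn{\sigma = 1} where absent.
#'
#' @param theoretical,experimental [scattering_curve()] objects with
#'   overlapping q ranges.
#' @return A list with elements `scale`, `chi` and `n` (points used).
#' @export
scale_to <- function(theoretical, experimental) {
  stopifnot(inherits(theoretical, "scattering_curve"),
            inherits(experimental, "scattering_curve"))
  qe <- experimental$q
  inside <- qe >= min(theoretical$q) & qe <= max(theoretical$q)
  if (!any(inside))
    stop_micello("overlap_error", "q ranges of the two curves do not overlap")
  qe <- qe[inside]
  Ie <- experimental$intensity[inside]
  sig <- if (is.null(experimental$sigma)) rep(1, length(qe)) else
    experimental$sigma[inside]
  sig[sig == 0] <- min(sig[sig > 0], 1)
  It <- approx(theoretical$q, theoretical$intensity, xout = qe)$y
  denom <- sum((It / sig)^2)
  if (denom == 0)
    stop_micello("undefined_scale", "theoretical curve is identically zero")
  s <- sum(Ie * It / sig^2) / denom
  ss <- sum(((Ie - s * It) / sig)^2)
  list(scale = s, chi = sqrt(ss / max(1L, length(qe) - 1L)), n = length(qe))
}
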