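## Core containers: pair distributions, bead models, ground truths.

#' Construct a pair-distance distribution
#'
#' `p(r)` is the contrast-weighted histogram of intra-particle scatterer
#' pair distances; it vanishes at `r = 0` and for `r >= D_max` (the maximum
#' particle dimension).  When produced by the indirect Fourier transform the
#' B-spline coefficients and basis are carried along.
#'
#' @param r Strictly increasing grid in Angstrom starting at 0.
#' @param p Values of p(r) on `r` (arbitrary units).
#' @param dmax Maximum dimension in Angstrom.
#' @param coefficients Optional spline coefficients (IFT output).
#' @param basis Optional [spline_basis()] descriptor.
#' @return An object of class `pair_distribution`.
#' @export
pair_distribution <- function(r, p, dmax, coefficients = NULL, basis = NULL) {
  r <- as.numeric(r); p <- as.numeric(p)
  if (length(r) != length(p))
    stop_micello("invariant_violation", "r and p lengths differ")
  if (any(diff(r) <= 0))
    stop_micello("invariant_violation", "r must be strictly increasing")
  if (r[1L] == 0 && abs(p[1L]) > 1e-8 * max(abs(p)))
    stop_micello("invariant_violation", "p(0) must be zero")
  if (!is.finite(dmax) || dmax <= 0)
    stop_micello("invariant_violation", "dmax must be positive")
  structure(list(r = r, p = p, dmax = dmax,
                 coefficients = coefficients, basis = basis),
            class = "pair_distribution")
}

#' @export
print.pair_distribution <- function(x, ...) {
  cat(sprintf("<pair_distribution> %d points, D_max = %.2f A, peak at r = %.2f A\n",
              length(x$r), x$dmax, x$r[which.max(x$p)]))
  invisible(x)
}

#' @export
plot.pair_distribution <- function(x, ...) {
  plot(x$r, x$p, type = "l", xlab = "r [Angstrom]", ylab = "p(r)", ...)
  abline(h = 0, lty = 3)
  invisible(x)
}

#' Read / write p(r) tables
#'
#' Three whitespace-delimited columns `r p sigma` (sigma optional, written
#' as 0 when unknown); `#`-comment header carries `dmax`.
#'
#' @param path File path.
#' @return [pair_distribution()] for the reader; `path` invisibly for the
#'   writer.
#' @export
read_pr <- function(path) {
  if (!file.exists(path)) stop_micello("io_error", "file not found: '%s'", path)
  tab <- parse_numeric_table(path, 2L, 3L, "p(r) table")
  dmax <- NA_real_
  for (h in tab$header) {
    kv <- regmatches(h, regexec("dmax\\s*:\\s*([0-9.eE+-]+)", h))[[1L]]
    if (length(kv) == 2L) dmax <- as.numeric(kv[2L])
  }
  r <- tab$mat[, 1L]
  if (is.na(dmax)) dmax <- max(r)
  pair_distribution(r = r, p = tab$mat[, 2L], dmax = dmax)
}

#' @rdname read_pr
#' @param pr A [pair_distribution()].
#' @export
write_pr <- function(pr, path) {
  stopifnot(inherits(pr, "pair_distribution"))
  writeLines(c("# columns: r [Angstrom]  p(r)  sigma",
               sprintf("# dmax: %.6g", pr$dmax),
               paste(formatC(pr$r, digits = 8, format = "g"),
                     formatC(pr$p, digits = 8, format = "g"),
                     "0", sep = "  ")), path)
  invisible(path)
}

#' Construct a bead model
#'
#' A set of point scatterers (positions in Angstrom, scattering weights in
#' arbitrary units, negative allowed for core--shell contrast) standing in
#' for a micelle or molecule in Debye-equation forward scattering.
#'
#' @param positions n x 3 numeric matrix, Angstrom.
#' @param weights Scattering weights, length n (default all 1).
#' @param label Optional character label.
#' @return An object of class `bead_model`.
#' @export
bead_model <- function(positions, weights = rep(1, nrow(positions)),
                       label = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L)
    stop_micello("invariant_violation", "positions must be n x 3")
  if (nrow(positions) < 1L)
    stop_micello("empty_input", "bead model must contain at least one bead")
  if (any(!is.finite(positions)))
    stop_micello("invariant_violation", "positions must be finite")
  weights <- as.numeric(weights)
  if (length(weights) != nrow(positions))
    stop_micello("invariant_violation", "weights length differs from bead count")
  if (all(weights == 0))
    stop_micello("invariant_violation", "at least one weight must be nonzero")
  structure(list(positions = unname(positions), weights = weights,
                 label = label), class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("<bead_model> %d beads%s\n", nrow(x$positions),
              if (is.null(x$label)) "" else paste0(" (", x$label, ")")))
  invisible(x)
}

#' Ground truth descriptor for a synthetic particle
#'
#' Records the shape family, semi-axes, maximum dimension, radius of
#' gyration and axial ratio that a synthetic generator promises, so that
#' downstream recovery can be scored against a known answer.  For a uniform
#' ellipsoid with semi-axes \eqn{a \ge b \ge c}: \eqn{D_{max} = 2a},
#' \eqn{R_g = \sqrt{(a^2+b^2+c^2)/5}}, axial ratio \eqn{a/b}.
#'
#' @param shape One of `"sphere"`, `"prolate"`, `"core-shell"`, `"aggregate"`.
#' @param semi_axes Numeric length-3, Angstrom, non-increasing.
#' @param dmax,rg,axial_ratio Closed-form values.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(shape, semi_axes, dmax, rg, axial_ratio) {
  shape <- match.arg(shape, c("sphere", "prolate", "core-shell", "aggregate"))
  structure(list(shape = shape, semi_axes = semi_axes, dmax = dmax,
                 rg = rg, axial_ratio = axial_ratio), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s: D_max = %.2f A, Rg = %.3f A, axial ratio = %.3f\n",
              x$shape, x$dmax, x$rg, x$axial_ratio))
  invisible(x)
}
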