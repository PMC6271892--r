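## Indirect Fourier transformation: p(r) as a regularized cubic B-spline
## expansion fitted to a measured scattering curve.

#' Cubic B-spline basis on [0, D_max]
#'
#' A clamped cubic B-spline basis of `n_basis` functions on a uniform knot
#' vector over `[0, dmax]`.  Each basis function is non-negative and
#' vanishes outside `[0, dmax]`; together they reproduce any cubic inside
#' the span.  In the IFT the first and last coefficients are pinned to zero
#' so that p(0) = 0 and p(D_max) = 0.
#'
#' @param n_basis Number of basis functions (>= 8).
#' @param dmax Support end, Angstrom.
#' @return An object of class `spline_basis`.
#' @export
spline_basis <- function(n_basis, dmax) {
  if (n_basis < 8L)
    stop_micello("invariant_violation", "n_basis must be >= 8")
  if (!(dmax > 0)) stop_micello("invariant_violation", "dmax must be positive")
  breaks <- seq(0, dmax, length.out = n_basis - 2L)
  knots <- c(rep(0, 3L), breaks, rep(dmax, 3L))
  structure(list(n = as.integer(n_basis), dmax = dmax, knots = knots),
            class = "spline_basis")
}

#' Evaluate a spline basis
#'
#' @param basis A [spline_basis()].
#' @param r Evaluation points, Angstrom.
#' @return Matrix `length(r) x n_basis`; zero outside `[0, dmax]`.
#' @export
basis_eval <- function(basis, r) {
  stopifnot(inherits(basis, "spline_basis"))
  inside <- r >= 0 & r <= basis$dmax
  out <- matrix(0, length(r), basis$n)
  if (any(inside))
    out[inside, ] <- splines::splineDesign(basis$knots, r[inside], ord = 4L,
                                           outer.ok = TRUE)
  out
}

## Quadrature nodes: >= 25 points per knot span, plus trapezoid weights.
basis_quadrature <- function(basis, per_span = 25L) {
  nspan <- basis$n - 3L
  r <- seq(0, basis$dmax, length.out = nspan * per_span + 1L)
  h <- r[2L] - r[1L]
  w <- rep(h, length(r)); w[c(1L, length(r))] <- h / 2
  list(r = r, w = w)
}

trapz_weights <- function(x) {
  n <- length(x)
  if (n == 1L) return(1)
  w <- numeric(n)
  w[1L] <- (x[2L] - x[1L]) / 2
  w[n] <- (x[n] - x[n - 1L]) / 2
  if (n > 2L) w[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / 2
  w
}

#' Build the IFT design matrix
#'
#' Entry (k, i) is \eqn{4\pi \int_0^{D_{max}} \phi_i(r) \sin(q_k r)/(q_k r)
#' dr} (trapezoid quadrature, 25 nodes per knot span): the intensity the
#' i-th spline would scatter at q_k.  When a slit profile is supplied every
#' column is smeared through the same kernel, so smeared data can be fitted
#' directly.
#'
#' @param basis A [spline_basis()].
#' @param q_grid Positive q values.
#' @param smear_profile Optional [slit_profile()].
#' @return Matrix `length(q_grid) x n_basis`.
#' @export
build_design_matrix <- function(basis, q_grid, smear_profile = NULL) {
  q_grid <- as.numeric(q_grid)
  if (any(q_grid <= 0))
    stop_micello("invariant_violation", "q_grid must be positive")
  quad <- basis_quadrature(basis)
  B <- basis_eval(basis, quad$r) * quad$w  # weight rows for the r integral
  unsmeared <- function(qv) 4 * pi * (sinc(outer(qv, quad$r)) %*% B)
  if (is.null(smear_profile) || smear_profile$type == "delta")
    return(unsmeared(q_grid))
  t <- smear_profile$t
  vt <- 2 * trapz_weights(t) * smear_profile$w  # sums to ~1
  K <- length(q_grid); M <- length(t)
  qext <- sqrt(outer(q_grid^2, t^2, `+`))       # K x M extended q nodes
  A0 <- unsmeared(as.numeric(qext))             # (K*M) x N, column-major
  A <- matrix(0, K, basis$n)
  for (m in seq_len(M))
    A <- A + vt[m] * A0[(m - 1L) * K + seq_len(K), , drop = FALSE]
  A
}

#' Solve the stabilized least-squares system
#'
#' Minimizes \eqn{\sum_k [(I_k - (Ac)_k)/\sigma_k]^2 + \lambda \sum_i
#' (c_{i+1} - 2c_i + c_{i-1})^2} — a second-difference smoothness penalty —
#' through the QR factorization of the augmented system.  With
#' `pin_ends = TRUE` (the default, used by [ift_fit()]) the first and last
#' coefficients are fixed at zero to enforce p(0) = p(D_max) = 0.
#'
#' @param design Design matrix from [build_design_matrix()].
#' @param curve The [scattering_curve()] being fitted (rows must match).
#' @param lambda Stabilization weight (>= 0).
#' @param pin_ends Pin the first/last coefficients to zero?
#' @return Numeric coefficient vector (full length, pinned entries zero).
#' @export
solve_coefficients <- function(design, curve, lambda, pin_ends = TRUE) {
  stopifnot(inherits(curve, "scattering_curve"))
  if (lambda < 0) stop_micello("invariant_violation", "lambda must be >= 0")
  if (nrow(design) != length(curve$q))
    stop_micello("invariant_violation", "design rows != curve length")
  N <- ncol(design)
  sig <- if (is.null(curve$sigma)) rep(1, nrow(design)) else curve$sigma
  sig[sig <= 0] <- min(c(sig[sig > 0], 1))
  free <- if (pin_ends) 2:(N - 1L) else seq_len(N)
  if (lambda == 0 && nrow(design) < length(free))
    stop_micello("rank_error",
                 "underdetermined at lambda = 0 (%d points, %d coefficients); use lambda > 0",
                 nrow(design), length(free))
  D2 <- matrix(0, N - 2L, N)
  for (j in seq_len(N - 2L)) D2[j, j:(j + 2L)] <- c(1, -2, 1)
  Aw <- design / sig
  M <- rbind(Aw[, free, drop = FALSE],
             sqrt(lambda) * D2[, free, drop = FALSE])
  rhs <- c(curve$intensity / sig, numeric(nrow(D2)))
  dec <- qr(M)
  if (dec$rank < length(free))
    stop_micello("rank_error",
                 "singular stabilized system (rank %d < %d); increase lambda",
                 dec$rank, length(free))
  cfree <- qr.coef(dec, rhs)
  cc <- numeric(N)
  cc[free] <- cfree
  cc
}

## Automatic stabilization weight: chi^2(lambda) is non-decreasing in
## lambda, so take the LARGEST lambda whose chi^2 stays within the target —
## the smoothest p(r) the data do not reject.  With uncertainties present
## the target is the discrepancy-principle value (chi^2 = n, i.e. residuals
## at the noise level) unless even the least-smoothed fit cannot reach it;
## without them (and as the fallback) the target is 105% of the achievable
## minimum.
choose_lambda <- function(design, curve, pin_ends = TRUE, grid = NULL) {
  N <- ncol(design)
  D2 <- matrix(0, N - 2L, N)
  for (j in seq_len(N - 2L)) D2[j, j:(j + 2L)] <- c(1, -2, 1)
  sig <- if (is.null(curve$sigma)) rep(1, nrow(design)) else curve$sigma
  sig[sig <= 0] <- min(c(sig[sig > 0], 1))
  lam_ref <- sum((design / sig)^2) / sum(D2^2)
  if (is.null(grid)) grid <- lam_ref * 10^seq(-10, 2, length.out = 31L)
  chi2 <- vapply(grid, function(l) {
    cc <- tryCatch(solve_coefficients(design, curve, l, pin_ends),
                   error = function(e) rep(NA_real_, N))
    if (anyNA(cc)) return(NA_real_)
    sum(((curve$intensity - design %*% cc) / sig)^2)
  }, numeric(1L))
  ok <- which(is.finite(chi2))
  if (length(ok) == 0L) return(lam_ref * 1e-4)
  target <- 1.05 * min(chi2[ok])
  if (!is.null(curve$sigma))
    target <- max(target, length(curve$q))
  grid[max(ok[chi2[ok] <= target])]
}

#' Indirect Fourier transformation of a scattering curve
#'
#' Fits the pair-distance distribution \eqn{p(r) = \sum_i c_i \phi_i(r)}
#' (cubic B-splines on `[0, dmax]`, first/last coefficients pinned to zero)
#' to a measured curve by stabilized least squares: the spline transform of
#' each basis function is matched to the data and a second-difference
#' smoothness penalty with weight `lambda` suppresses the oscillations that
#' plague unregularized finite-window inversion.  Low-q points below
#' `q_min_cut` are removed first (inter-particle interference suppression).
#' Smeared data may be fitted directly by passing the slit profile, which
#' smears the design columns instead of desmearing the data.
#'
#' Non-negativity of p(r) is not enforced; negative tail oscillation is
#' reported as a diagnostic (see [scan_dmax()]).
#'
#' @param curve A [scattering_curve()].
#' @param dmax Assumed maximum dimension, Angstrom (fit support; choose
#'   generously or scan with [scan_dmax()]).
#' @param n_basis Number of spline functions (default 20).
#' @param lambda Stabilization weight, or `"auto"` for an L-curve corner
#'   over a log grid.
#' @param q_min_cut Drop data with q below this, 1/Angstrom (default 0.04).
#' @param smear_profile [slit_profile()] when fitting smeared data.
#' @param r_points Length of the evaluated p(r) grid (default 201).
#' @return An object of class `ift` with components `pr`
#'   ([pair_distribution()]), `coefficients`, `lambda`, `fitted`, `chi2`,
#'   `chi2_reduced`, `n_excluded`, `data` (the points fitted), `basis`.
#' @seealso [scan_dmax()], [dmax_from_pr()], [shape_report()]
#' @export
ift_fit <- function(curve, dmax, n_basis = 20L, lambda = "auto",
                    q_min_cut = 0.04, smear_profile = NULL, r_points = 201L) {
  stopifnot(inherits(curve, "scattering_curve"))
  if (!(dmax > 0)) stop_micello("invariant_violation", "dmax must be positive")
  if (n_basis < 8L) stop_micello("invariant_violation", "n_basis must be >= 8")
  if (curve$smeared && is.null(smear_profile))
    stop_micello("state_error",
                 "curve is slit-smeared: desmear it first or pass smear_profile")
  keep <- curve$q >= q_min_cut
  n_excluded <- sum(!keep)
  used <- scattering_curve(curve$q[keep], curve$intensity[keep],
                           sigma = curve$sigma[keep], smeared = curve$smeared,
                           meta = curve$meta)
  if (length(used$q) < n_basis)
    stop_micello("data_deficit", "only %d usable points for %d basis functions",
                 length(used$q), n_basis)
  basis <- spline_basis(n_basis, dmax)
  design <- build_design_matrix(basis, used$q,
                                if (curve$smeared) smear_profile else NULL)
  if (identical(lambda, "auto")) lambda <- choose_lambda(design, used)
  cc <- solve_coefficients(design, used, lambda, pin_ends = TRUE)
  fit <- as.numeric(design %*% cc)
  sig <- if (is.null(used$sigma)) rep(1, length(fit)) else used$sigma
  sig[sig <= 0] <- min(c(sig[sig > 0], 1))
  chi2 <- sum(((used$intensity - fit) / sig)^2)
  r <- seq(0, dmax, length.out = r_points)
  p <- as.numeric(basis_eval(basis, r) %*% cc)
  p[c(1L, r_points)] <- 0  # exact by construction; kill rounding fuzz
  structure(list(pr = pair_distribution(r, p, dmax, coefficients = cc,
                                        basis = basis),
                 coefficients = cc, lambda = lambda,
                 fitted = fit, chi2 = chi2,
                 chi2_reduced = chi2 / max(1L, length(fit) - (n_basis - 2L)),
                 n_excluded = n_excluded, q_min_cut = q_min_cut,
                 data = used, basis = basis, smear_profile = smear_profile,
                 call = match.call()),
            class = "ift")
}

#' @export
print.ift <- function(x, ...) {
  cat(sprintf("Indirect Fourier transform fit\n  %d points (%d excluded below q = %.3g), %d splines on [0, %.4g] A\n  lambda = %.4g, chi2 = %.4g (reduced %.3g)\n",
              length(x$data$q), x$n_excluded, x$q_min_cut, x$basis$n,
              x$basis$dmax, x$lambda, x$chi2, x$chi2_reduced))
  invisible(x)
}

#' @export
coef.ift <- function(object, ...) object$coefficients

#' @export
fitted.ift <- function(object, ...) object$fitted

#' @export
residuals.ift <- function(object, type = c("raw", "weighted"), ...) {
  type <- match.arg(type)
  r <- object$data$intensity - object$fitted
  if (type == "weighted" && !is.null(object$data$sigma))
    r <- r / object$data$sigma
  r
}

#' Predict model intensity from an IFT fit
#'
#' Evaluates the fitted p(r)'s transform on a new q grid; by default the
#' unsmeared (ideal pinhole) curve, or the slit-smeared one if the fit was
#' made against smeared data and `smeared = TRUE`.
#'
#' @param object An `ift` fit.
#' @param q q grid (default: the fitted data's grid).
#' @param smeared Return the slit-smeared model curve?
#' @param ... Unused.
#' @return A [scattering_curve()].
#' @export
predict.ift <- function(object, q = object$data$q, smeared = FALSE, ...) {
  prof <- if (smeared) object$smear_profile else NULL
  A <- build_design_matrix(object$basis, q, prof)
  scattering_curve(q, as.numeric(A %*% object$coefficients),
                   smeared = smeared, meta = list(label = "ift prediction"))
}

#' @export
summary.ift <- function(object, ...) {
  rep <- tryCatch(shape_report(object$pr), error = function(e) NULL)
  structure(list(fit = object, shape = rep,
                 i0 = 4 * pi * trapz(object$pr$r, object$pr$p)),
            class = "summary.ift")
}

#' @export
print.summary.ift <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  I(0) = %.4g\n", x$i0))
  if (!is.null(x$shape)) print(x$shape)
  invisible(x)
}

#' @export
plot.ift <- function(x, which = c("fit", "pr"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  if (length(which) > 1L) {
    op <- par(mfrow = c(1, length(which))); on.exit(par(op))
  }
  if ("fit" %in% which) {
    d <- x$data
    plot(d$q, d$intensity, log = "y", pch = 16, cex = 0.4,
         xlab = "q [1/Angstrom]", ylab = "I(q)", main = "Fit", ...)
    lines(d$q, x$fitted, col = 2, lwd = 2)
  }
  if ("pr" %in% which) {
    plot(x$pr, main = "p(r)")
  }
  invisible(x)
}

#' Scan candidate D_max values
#'
#' Runs [ift_fit()] at each candidate support length and tabulates the
#' residual chi-square and a tail-negativity score (the fraction of
#' integrated |p| that is negative — oscillating tails signal an
#' over-generous or badly mismatched support).  The recommendation is the
#' smallest candidate whose chi-square is within 5% of the scan minimum and
#' whose negativity score is below `score_threshold`.  When chi-square
#' decreases monotonically to the last candidate (no interior optimum) the
#' scan is flagged: all candidates are likely below the true D_max.
#'
#' @param curve A [scattering_curve()].
#' @param candidates Increasing D_max candidates, Angstrom.
#' @param n_basis,lambda,q_min_cut,smear_profile Passed to [ift_fit()].
#' @param score_threshold Tail-negativity acceptance threshold.
#' @return A data.frame (`dmax`, `chi2`, `tail_score`) of class
#'   `scan_dmax`, with attributes `recommended` and `flag`.
#' @export
scan_dmax <- function(curve, candidates, n_basis = 20L, lambda = "auto",
                      q_min_cut = 0.04, smear_profile = NULL,
                      score_threshold = 0.05) {
  if (any(diff(candidates) <= 0))
    stop_micello("invariant_violation", "candidates must be increasing")
  rows <- lapply(candidates, function(d) {
    f <- ift_fit(curve, d, n_basis = n_basis, lambda = lambda,
                 q_min_cut = q_min_cut, smear_profile = smear_profile)
    p <- f$pr$p
    score <- sum(pmax(-p, 0)) / max(sum(abs(p)), .Machine$double.eps)
    data.frame(dmax = d, chi2 = f$chi2, tail_score = score)
  })
  tab <- do.call(rbind, rows)
  flag <- NULL
  best <- min(tab$chi2)
  ok <- tab$chi2 <= 1.05 * best & tab$tail_score <= score_threshold
  if (length(candidates) > 2L && all(diff(tab$chi2) < 0)) {
    flag <- "chi2 decreases monotonically across the scan; true D_max likely exceeds all candidates"
    rec <- candidates[length(candidates)]
  } else if (any(ok)) {
    rec <- tab$dmax[which(ok)[1L]]
  } else {
    rec <- tab$dmax[which.min(tab$chi2)]
    flag <- "no candidate met both the chi2 and tail-score criteria; chi2 minimum returned"
  }
  structure(tab, class = c("scan_dmax", "data.frame"),
            recommended = rec, flag = flag)
}

#' @export
print.scan_dmax <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, ...)
  cat(sprintf("recommended D_max: %.4g A\n", attr(x, "recommended")))
  if (!is.null(attr(x, "flag"))) cat("flag:", attr(x, "flag"), "\n")
  invisible(x)
}
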