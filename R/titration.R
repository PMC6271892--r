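## Henderson-Hasselbalch pKa fitting of titration curves.

hh_model <- function(pH, lambda_acid, lambda_base, pKa) {
  lambda_acid + (lambda_base - lambda_acid) / (1 + 10^(pKa - pH))
}

#' Fit the Henderson-Hasselbalch sigmoid to a titration curve
#'
#' Nonlinear least squares of \eqn{\lambda(pH) = \lambda_A + (\lambda_B -
#' \lambda_A)/(1 + 10^{pKa - pH})}: the signal transitions between an acid
#' plateau \eqn{\lambda_A} and a base plateau \eqn{\lambda_B}, centered at
#' the pKa.  Automatic initialization takes the plateaus from the three
#' extreme points on each side and the pKa from the half-height crossing;
#' pKa is box-constrained to \[0, 14\].  Points are unweighted unless
#' `weights` is given.  The fit is reported in canonical orientation
#' (`plateau_acid` is the fitted value at low pH), so data where the signal
#' decreases with pH fit equally well.
#'
#' @param curve A [titration_curve()] with at least 5 points spanning both
#'   sides of the transition.
#' @param init Optional named list `lambda_acid`, `lambda_base`, `pKa`.
#' @param weights Optional fit weights.
#' @return An object of class `hh_fit`: `pKa`, `pKa_se`, `plateau_acid`,
#'   `plateau_base`, `rms`, plus the underlying `nls` object.
#' @examples
#' tc <- make_titration(7.2, seed = 1)
#' hh_fit(tc)
#' @export
hh_fit <- function(curve, init = NULL, weights = NULL) {
  stopifnot(inherits(curve, "titration_curve"))
  pH <- curve$pH; lam <- curve$wavelength
  if (length(pH) < 5L)
    stop_micello("data_deficit", "need at least 5 titration points")
  if (is.null(init)) {
    k <- min(3L, length(pH) %/% 2L)
    la <- mean(head(lam, k)); lb <- mean(tail(lam, k))
    half <- (la + lb) / 2
    ic <- which.min(abs(lam - half))
    init <- list(lambda_acid = la, lambda_base = lb, pKa = pH[ic])
  }
  df <- data.frame(pH = pH, lam = lam)
  nls_args <- list(lam ~ hh_model(pH, lambda_acid, lambda_base, pKa),
                   data = df, start = init,
                   lower = c(-Inf, -Inf, 0), upper = c(Inf, Inf, 14),
                   control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!is.null(weights)) nls_args$weights <- weights
  fit <- tryCatch(
    do.call(minpack.lm::nlsLM, nls_args),
    error = function(e)
      stop_micello("fit_error", "Henderson-Hasselbalch fit failed: %s",
                   conditionMessage(e)))
  co <- coef(fit)
  pKa <- unname(co["pKa"])
  if (pKa <= min(pH) || pKa >= max(pH))
    stop_micello("non_identifiable",
                 "fitted pKa (%.2f) falls outside the measured pH range [%.2f, %.2f]: no transition in the data",
                 pKa, min(pH), max(pH))
  se <- tryCatch(summary(fit)$coefficients["pKa", "Std. Error"],
                 error = function(e) NA_real_)
  res <- residuals(fit)
  structure(list(pKa = pKa, pKa_se = unname(se),
                 plateau_acid = unname(co["lambda_acid"]),
                 plateau_base = unname(co["lambda_base"]),
                 rms = sqrt(mean(res^2)),
                 nls = fit, data = curve, call = match.call()),
            class = "hh_fit")
}

#' @export
print.hh_fit <- function(x, ...) {
  cat(sprintf("Henderson-Hasselbalch fit\n  pKa = %.2f +/- %.2f\n  plateaus: %.1f nm (acid) -> %.1f nm (base)\n  residual RMS %.3f nm over %d points\n",
              x$pKa, x$pKa_se, x$plateau_acid, x$plateau_base, x$rms,
              length(x$data$pH)))
  invisible(x)
}

#' @export
summary.hh_fit <- function(object, ...) summary(object$nls, ...)

#' @export
coef.hh_fit <- function(object, ...)
  c(pKa = object$pKa, plateau_acid = object$plateau_acid,
    plateau_base = object$plateau_base)

#' @export
predict.hh_fit <- function(object, pH = object$data$pH, ...)
  hh_model(pH, object$plateau_acid, object$plateau_base, object$pKa)

#' @export
residuals.hh_fit <- function(object, ...)
  object$data$wavelength - predict(object)

#' @export
fitted.hh_fit <- function(object, ...) predict(object)

#' @export
plot.hh_fit <- function(x, ...) {
  plot(x$data$pH, x$data$wavelength, xlab = "pH",
       ylab = "emission wavelength [nm]", ...)
  ph <- seq(min(x$data$pH), max(x$data$pH), length.out = 200)
  lines(ph, predict(x, ph), col = 2, lwd = 2)
  abline(v = x$pKa, lty = 3)
  invisible(x)
}
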