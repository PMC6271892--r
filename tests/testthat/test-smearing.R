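test_that("slit kernels are normalized and the delta kernel is the identity", {
  prof <- slit_profile("trapezoid", t1 = 0.05, t_max = 0.2)
  # half-line integral = 1/2
  tw <- prof$t; w <- prof$w
  expect_equal(sum(diff(tw) * (head(w, -1) + tail(w, -1)) / 2), 0.5,
               tolerance = 1e-10)
  sp <- small_prolate()
  dl <- slit_smear(sp$curve, slit_profile("delta"))
  expect_equal(dl$intensity, sp$curve$intensity)
  expect_true(dl$smeared)
  # a constant curve is preserved by the normalized kernel
  const <- scattering_curve(seq(0.02, 0.6, by = 0.01), rep(3.3, 59))
  smc <- slit_smear(const, prof)
  expect_rel_equal(smc$intensity, rep(3.3, 59), 1e-6)
})

test_that("smearing fills in the sphere form-factor zeros", {
  q <- seq(0.02, 0.6, by = 0.004)
  ff <- sphere_form_factor(30, q)
  sm <- slit_smear(ff, slit_profile("trapezoid", 0.05, 0.2))
  expect_lt(min(ff$intensity), 1e-5)   # grid point closest to the true zero
  expect_gt(min(sm$intensity), 10 * min(ff$intensity))  # minima filled in
  # ordering is preserved for a monotonically decreasing curve
  g <- scattering_curve(q, exp(-q^2 * 30))
  smg <- slit_smear(g, slit_profile("trapezoid", 0.05, 0.2))
  # ordering holds where the operator does not lean on the extrapolated
  # tail (q <= sqrt(qmax^2 - tmax^2))
  inside <- smg$q <= sqrt(max(q)^2 - 0.2^2)
  expect_true(all(diff(smg$intensity[inside]) < 0))
})

test_that("desmearing undoes slit smearing within 3% at mid q", {
  sp <- small_prolate()
  prof <- slit_profile("trapezoid", 0.05, 0.2)
  sm <- slit_smear(sp$curve, prof)
  de <- suppressWarnings(desmear(sm, prof, max_iter = 40L, tol = 1e-5))
  mid <- de$q >= 0.03 & de$q <= 0.4
  tru <- sp$curve$intensity[match(de$q, sp$curve$q)]
  expect_rel_equal(de$intensity[mid], tru[mid], 0.03)
  expect_false(de$smeared)
  # state guards
  expect_error(desmear(sp$curve, prof), class = "state_error")
  expect_error(slit_smear(sm, prof), class = "state_error")
})

test_that("desmear handles the delta kernel and negative intensities", {
  q <- seq(0.02, 0.3, by = 0.01)
  cur <- scattering_curve(q, exp(-q * 10), smeared = TRUE)
  out <- desmear(cur, slit_profile("delta"))
  expect_equal(out$intensity, cur$intensity)
  expect_equal(out$meta$desmear$iterations, 1L)
  neg <- scattering_curve(q, exp(-q * 10) - 0.5, smeared = TRUE)
  expect_warning(res <- desmear(neg, slit_profile("delta")), "clipped")
  expect_true(all(res$intensity > 0))
})

test_that("cubic smoothing reproduces cubics exactly and degrades to a global fit", {
  q <- seq(0.02, 0.6, length.out = 41)
  cubic <- 2 + 3 * q - 4 * q^2 + 5 * q^3
  cur <- scattering_curve(q, cubic)
  sm <- smooth_curve(cur, 11L)
  expect_equal(sm$intensity, cubic, tolerance = 1e-9)
  # window equal to the curve length: one global cubic
  q5 <- seq(0.1, 0.5, by = 0.1)
  y5 <- c(1, 4, 2, 5, 3)
  glob <- smooth_curve(scattering_curve(q5, y5), 5L)
  fit <- lm(y5 ~ q5 + I(q5^2) + I(q5^3))
  expect_equal(glob$intensity, unname(fitted(fit)), tolerance = 1e-8)
  expect_error(smooth_curve(scattering_curve(q5, y5), 7L),
               class = "invariant_violation")
  expect_error(smooth_curve(cur, 10L), class = "invariant_violation")
})

test_that("smoothing attenuates white noise by the fitted-polynomial factor", {
  # analytic variance factor of the central point of a cubic fit over a
  # uniform window: e' (X'X)^-1 e with X = [1, x, x^2, x^3]
  w <- 11L
  x <- seq(-5, 5)
  X <- cbind(1, x, x^2, x^3)
  factor_theory <- sqrt(solve(crossprod(X))[1L, 1L])
  set.seed(12)
  q <- seq(0.02, 0.6, length.out = 600)
  reduction <- replicate(10, {
    noise <- rnorm(600)
    sm <- smooth_curve(scattering_curve(q, 10 + noise), w)
    sd(sm$intensity[20:580] - 10)
  })
  expect_equal(mean(reduction), factor_theory, tolerance = 0.1)
})

test_that("absolute scaling follows the water calibration and guards reapplication", {
  q <- seq(0.02, 0.3, by = 0.01)
  cur <- scattering_curve(q, rep(2, length(q)), sigma = rep(0.1, length(q)))
  idn <- absolute_scale(cur, transmission = 1, measured_water_level = 1.68e-2)
  expect_equal(idn$intensity, cur$intensity)
  half <- absolute_scale(cur, transmission = 0.5, measured_water_level = 1.68e-2)
  expect_equal(half$intensity, 2 * cur$intensity)
  expect_equal(half$sigma, 2 * cur$sigma)
  expect_error(absolute_scale(idn, 1, 1.68e-2), class = "state_error")
  expect_error(absolute_scale(cur, 1, 0), class = "scaling_error")
  expect_error(absolute_scale(cur, 1.4, 1), class = "invariant_violation")
})
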