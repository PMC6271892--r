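test_that("Debye sum reproduces the two-bead and single-bead closed forms", {
  d <- 10
  m <- bead_model(rbind(c(0, 0, 0), c(0, 0, d)))
  q <- c(1e-4, 0.05, 0.1, 0.31, 0.6)
  I <- debye_intensity(m, q)$intensity
  expect_equal(I, 2 * (1 + sin(q * d) / (q * d)), tolerance = 1e-12)
  expect_equal(I[1L], 4, tolerance = 1e-6)  # (sum of weights)^2 at q -> 0
  one <- bead_model(matrix(c(1, 2, 3), 1L), weights = 2.5)
  expect_equal(debye_intensity(one, q)$intensity, rep(2.5^2, 5L))
  expect_error(debye_intensity(m, c(0, 0.1)), class = "invariant_violation")
})

test_that("Debye intensity is invariant under rigid motions", {
  m <- make_ellipsoid(15, 10, 8, 150, seed = 3)$model
  q <- seq(0.05, 0.5, by = 0.05)
  I0 <- debye_intensity(m, q)$intensity
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- bead_model(sweep(m$positions %*% t(R), 2L, c(5, -3, 11), `+`),
                      m$weights)
  expect_rel_equal(debye_intensity(moved, q)$intensity, I0, 1e-12)
})

test_that("sphere form factor has the textbook limits and first zero", {
  ff <- sphere_form_factor(20, c(1e-5, 0.05))
  expect_equal(ff$intensity[1L], 1, tolerance = 1e-8)
  # first zero of the amplitude: root of tan(x) = x, by bisection
  f <- function(x) sin(x) - x * cos(x)
  lo <- 4; hi <- 5
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
  }
  x0 <- (lo + hi) / 2
  expect_equal(x0, 4.4934, tolerance = 1e-4)
  qz <- x0 / 20
  expect_lt(sphere_form_factor(20, qz)$intensity, 1e-10)
  # Guinier: ln I = -q^2 R^2 / 5 for qR < 1
  q <- seq(0.005, 0.045, by = 0.005)
  expect_equal(log(sphere_form_factor(20, q)$intensity), -q^2 * 20^2 / 5,
               tolerance = 0.02)
})

test_that("bead-sphere Debye matches the analytic form factor within 2%", {
  sc <- sphere_debye()  # 20000 beads, R = 20, qR <= 6
  ff <- sphere_form_factor(20, sc$q)
  In <- sc$intensity / sc$intensity[1L] * ff$intensity[1L]
  # relative comparison is meaningful only away from the form-factor zeros
  ok <- ff$intensity > 1e-2
  expect_rel_equal(In[ok], ff$intensity[ok], 0.02)
})

test_that("exact pair histogram matches closed forms", {
  two <- bead_model(rbind(c(0, 0, 0), c(0, 0, 30)))
  pr <- pr_exact(two, 1)
  expect_equal(pr$dmax, 30)
  expect_equal(sum(pr$p > 0), 1L)
  expect_equal(pr$r[pr$p > 0], 30.5)  # center of bin [30, 31), which holds 30
  expect_error(pr_exact(bead_model(matrix(0, 1, 3))),
               class = "degenerate_distribution")
  # uniform sphere histogram vs closed-form p(r), 3%
  sph <- sphere_beads()
  pre <- pr_exact(sph$model, 0.5)
  x <- pre$r / 40
  closed <- pre$r^2 * (1 - 1.5 * x + 0.5 * x^3)
  closed[x > 1] <- 0
  scale <- sum(pre$p) / sum(closed)
  mid <- pre$r > 4 & pre$r < 36
  expect_rel_equal(pre$p[mid], (scale * closed)[mid], 0.03)
})

test_that("back transform closes the loop with the Debye sum", {
  sph <- sphere_beads()
  sc <- sphere_debye()
  bt <- back_transform(pr_exact(sph$model, 0.25), sc$q)
  Sn <- sc$intensity / sc$intensity[1L]
  ok <- Sn > 1e-2  # away from the minima, where relative error is defined
  expect_rel_equal((bt$intensity / bt$intensity[1L])[ok], Sn[ok], 0.02)
  # I(0) identity and the zero distribution
  pr <- sphere_pr(15, 201)
  i0 <- back_transform(pr, 1e-5)$intensity
  r <- pr$r
  expect_equal(i0, 4 * pi * sum(diff(r) * (head(pr$p, -1) + tail(pr$p, -1)) / 2),
               tolerance = 1e-6)
  null_pr <- pair_distribution(r = c(0, 10, 20), p = c(0, 0, 0), dmax = 20)
  expect_equal(back_transform(null_pr, c(0.1, 0.2))$intensity, c(0, 0))
})

test_that("scale_to recovers an exact scale factor and calibrated chi", {
  q <- seq(0.02, 0.5, by = 0.01)
  th <- sphere_form_factor(25, q, i0 = 10)
  exp_curve <- scattering_curve(q, 3.7 * th$intensity)
  s <- scale_to(th, exp_curve)
  expect_equal(s$scale, 3.7, tolerance = 1e-10)
  expect_equal(s$chi, 0, tolerance = 1e-8)
  # chi ~ 1 for residuals at the declared noise level
  set.seed(99)
  chis <- replicate(20, {
    sig <- 0.05 * th$intensity
    noisy <- scattering_curve(q, th$intensity + rnorm(length(q), 0, sig),
                              sigma = sig)
    scale_to(th, noisy)$chi
  })
  expect_equal(mean(chis), 1, tolerance = 0.1)
  zero <- scattering_curve(q, rep(0, length(q)))
  expect_error(scale_to(zero, exp_curve), class = "undefined_scale")
  far <- scattering_curve(q + 10, th$intensity)
  expect_error(scale_to(far, exp_curve), class = "overlap_error")
})
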