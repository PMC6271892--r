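test_that("the spline basis is a clamped partition with compact support", {
  b <- spline_basis(12, 60)
  r <- seq(-5, 70, by = 0.5)
  B <- basis_eval(b, r)
  expect_true(all(B >= 0))
  inside <- r >= 0 & r <= 60
  expect_equal(rowSums(B)[inside], rep(1, sum(inside)), tolerance = 1e-10)
  expect_true(all(B[!inside, ] == 0))
  expect_error(spline_basis(6, 60), class = "invariant_violation")
})

test_that("design-matrix entries hit the q -> 0 limit and the transform", {
  b <- spline_basis(10, 50)
  A <- build_design_matrix(b, 1e-5)
  r <- seq(0, 50, length.out = 2001)
  B <- basis_eval(b, r)
  ints <- 4 * pi * apply(B, 2L, function(col)
    sum(diff(r) * (head(col, -1) + tail(col, -1)) / 2))
  expect_rel_equal(as.numeric(A), ints, 5e-3)  # quadrature-level agreement
  # design %*% c agrees with back_transform of the evaluated p(r)
  set.seed(2)
  cc <- c(0, runif(8), 0)
  q <- seq(0.02, 0.5, by = 0.02)
  Aq <- build_design_matrix(b, q)
  rg <- seq(0, 50, length.out = 2001)
  pr <- pair_distribution(rg, as.numeric(basis_eval(b, rg) %*% cc), 50)
  bt <- back_transform(pr, q)
  expect_rel_equal(as.numeric(Aq %*% cc), bt$intensity, 5e-3)
})

test_that("design columns are slit-smeared consistently with slit_smear", {
  b <- spline_basis(12, 50)
  prof <- slit_profile("trapezoid", 0.05, 0.2)
  q <- seq(0.02, 0.5, by = 0.01)
  set.seed(3)
  cc <- c(0, runif(10), 0)
  qd <- seq(0.005, 0.8, by = 0.002)
  dense <- scattering_curve(qd, as.numeric(build_design_matrix(b, qd) %*% cc))
  ref <- approx(slit_smear(dense, prof)$q, slit_smear(dense, prof)$intensity,
                xout = q)$y
  got <- as.numeric(build_design_matrix(b, q, prof) %*% cc)
  expect_rel_equal(got, ref, 5e-3)
})

test_that("the stabilized solver honours its penalty limits", {
  b <- spline_basis(14, 40)
  q <- seq(0.02, 0.6, by = 0.01)
  A <- build_design_matrix(b, q)
  truth <- sphere_form_factor(15, q, i0 = 100)
  # lambda -> infinity: the smoothness seminorm is driven to zero
  pen <- function(cc) sum(diff(cc, differences = 2)^2)
  chuge <- solve_coefficients(A, truth, 1e12)
  csmall <- solve_coefficients(A, truth, 1e-6)
  expect_lt(pen(chuge), 1e-8 * pen(csmall))
  # duplicated data rows leave the solution unchanged
  c1 <- solve_coefficients(A, truth, 0.5)
  ii <- rep(seq_along(q), each = 2L)
  dup <- scattering_curve(sort(c(q, q + 1e-9)), truth$intensity[ii])
  c2 <- solve_coefficients(A[ii, ], dup, 1)  # penalty doubles with data
  expect_equal(c1, c2, tolerance = 1e-6)
  # underdetermined at lambda = 0
  A8 <- build_design_matrix(spline_basis(30, 40), seq(0.05, 0.3, length.out = 10))
  short <- scattering_curve(seq(0.05, 0.3, length.out = 10), rep(1, 10))
  expect_error(solve_coefficients(A8, short, 0), class = "rank_error")
})

test_that("IFT of a noiseless sphere curve recovers the closed-form p(r)", {
  q <- seq(0.02, 0.6, by = 0.004)
  ff <- sphere_form_factor(20, q, i0 = 1000)
  f <- ift_fit(ff, dmax = 50, n_basis = 20L, lambda = "auto", q_min_cut = 0.04)
  truth <- sphere_pr(20, 201)
  p_hat <- f$pr$p / max(f$pr$p)
  p_true <- approx(truth$r, truth$p / max(truth$p), xout = pmin(f$pr$r, 40))$y
  p_true[f$pr$r > 40] <- 0
  expect_lt(max(abs(p_hat - p_true)), 0.05)            # within 5% of peak
  expect_equal(f$pr$r[which.max(f$pr$p)], 21, tolerance = 0.1)  # mode ~ 1.05 R
  # structural invariants of any fit
  expect_identical(f$pr$p[1L], 0)
  expect_identical(f$pr$p[length(f$pr$p)], 0)
  expect_equal(f$fitted, as.numeric(build_design_matrix(f$basis, f$data$q) %*%
                                      coef(f)))
  pred <- predict(f, q = f$data$q)
  expect_equal(pred$intensity, f$fitted, tolerance = 1e-10)
})

test_that("IFT handles degenerate inputs as documented", {
  q <- seq(0.05, 0.5, by = 0.005)
  zero <- scattering_curve(q, rep(0, length(q)))
  fz <- ift_fit(zero, 40, 10, lambda = 1)
  expect_equal(fz$pr$p, rep(0, length(fz$pr$p)))
  few <- scattering_curve(seq(0.05, 0.2, length.out = 12), rep(1, 12))
  expect_error(ift_fit(few, 40, 20), class = "data_deficit")
  sm <- scattering_curve(q, rep(1, length(q)), smeared = TRUE)
  expect_error(ift_fit(sm, 40), class = "state_error")
})

test_that("the D_max scan recovers a sphere diameter and flags misfit scans", {
  q <- seq(0.02, 0.6, by = 0.004)
  ff <- sphere_form_factor(20, q, i0 = 1000)
  set.seed(4)
  noisy <- scattering_curve(q, ff$intensity * (1 + rnorm(length(q), 0, 0.01)),
                            sigma = 0.01 * ff$intensity)
  sc <- scan_dmax(noisy, seq(30, 60, by = 5), n_basis = 20L)
  expect_lte(abs(attr(sc, "recommended") - 40), 5)  # within one grid step
  low <- scan_dmax(noisy, c(20, 24, 28), n_basis = 10L)
  expect_false(is.null(attr(low, "flag")))
  one <- scan_dmax(noisy, 45)
  expect_equal(attr(one, "recommended"), 45)
  expect_equal(nrow(one), 1L)
})
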