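test_that("ellipsoid ground truth matches the uniform-body closed forms", {
  e <- make_ellipsoid(10, 10, 10, n_beads = 200L, seed = 2)
  expect_equal(e$truth$rg, sqrt(3 / 5) * 10, tolerance = 1e-12)
  expect_equal(e$truth$dmax, 20)
  p <- make_ellipsoid(37.5, 21, 21, n_beads = 10L, seed = 2)
  expect_equal(p$truth$dmax, 75)
  expect_equal(p$truth$axial_ratio, 37.5 / 21, tolerance = 1e-12)
  expect_equal(p$truth$rg, sqrt((37.5^2 + 2 * 21^2) / 5), tolerance = 1e-12)
})

test_that("empirical Rg of the bead cloud converges to the closed form", {
  sph <- sphere_beads()  # n = 20000
  expect_equal(radius_of_gyration(sph$model, "uniform"), sph$truth$rg,
               tolerance = 0.02)
  # and the max pairwise distance is bounded by (and approaches) D_max
  pr <- pr_exact(sph$model, 0.5)
  expect_lte(pr$dmax, sph$truth$dmax + 1e-9)
  expect_gt(pr$dmax, 0.99 * sph$truth$dmax)
})

test_that("generators are reproducible under a fixed seed", {
  a <- make_ellipsoid(20, 15, 10, 300, seed = 5)
  b <- make_ellipsoid(20, 15, 10, 300, seed = 5)
  expect_identical(a$model$positions, b$model$positions)
  expect_false(identical(a$model$positions,
                         make_ellipsoid(20, 15, 10, 300, seed = 6)$model$positions))
  t1 <- make_titration(7.2, seed = 9)
  t2 <- make_titration(7.2, seed = 9)
  expect_identical(t1$wavelength, t2$wavelength)
  s1 <- make_solvated_box(NULL, 40, 200, 2.5, seed = 4)
  s2 <- make_solvated_box(NULL, 40, 200, 2.5, seed = 4)
  expect_identical(s1$atoms$x, s2$atoms$x)
})

test_that("generator preconditions are enforced", {
  expect_error(make_ellipsoid(10, 20, 5, 100, seed = 1),
               class = "invariant_violation")
  expect_error(make_ellipsoid(10, 10, 10, 5, seed = 1),
               class = "insufficient_sampling")
  expect_error(make_core_shell_sphere(30, 20, 1, 1, 100, seed = 1),
               class = "geometry_error")
  expect_error(make_titration(7, pH_grid = c(-1, 3, 5)),
               class = "invariant_violation")
})

test_that("core-shell contrast behaves in its degenerate and inverted limits", {
  q <- seq(0.02, 0.12, by = 0.02)  # qR <= 3: Monte-Carlo error stays small
  # equal weights: indistinguishable from a uniform sphere of r_shell
  cs <- make_core_shell_sphere(10, 25, 1, 1, 4000L, seed = 8)
  Ics <- debye_intensity(cs, q)
  ff <- sphere_form_factor(25, q)
  expect_rel_equal(Ics$intensity / Ics$intensity[1L],
                   ff$intensity / ff$intensity[1L], 0.06)
  # zero shell weight: the core alone scatters
  core_only <- make_core_shell_sphere(10, 25, 1, 0, 4000L, seed = 8)
  keep <- core_only$weights != 0
  Ico <- debye_intensity(bead_model(core_only$positions[keep, ], rep(1, sum(keep))),
                         q)
  ffc <- sphere_form_factor(10, q)
  expect_rel_equal(Ico$intensity / Ico$intensity[1L],
                   ffc$intensity / ffc$intensity[1L], 0.06)
  # inverted core dips well below the uniform sphere before its first zero
  qd <- seq(0.02, 0.12, by = 0.005)
  inv <- make_core_shell_sphere(15, 25, -1, 1, 4000L, seed = 8)
  Iinv <- debye_intensity(inv, qd)
  ffu <- sphere_form_factor(25, qd)
  expect_lt(min(Iinv$intensity / max(Iinv$intensity)),
            0.5 * min(ffu$intensity / max(ffu$intensity)))
})

test_that("aggregates are clash-free shells with buried tails", {
  agg <- make_aggregate(10, seed = 21)
  a <- agg$atoms
  pos <- as.matrix(a[, c("x", "y", "z")])
  # no two atoms of different monomers closer than the minimum separation
  d <- as.matrix(dist(pos))
  inter <- outer(a$group, a$group, `!=`)
  expect_gte(min(d[inter]), 1.5)
  # hydrophobic tails are closer to the center than hydrophilic heads
  ctr <- colMeans(pos)
  rad <- sqrt(rowSums(sweep(pos, 2L, ctr)^2))
  expect_lt(mean(rad[a$part == "hydrophobic"]),
            mean(rad[a$part == "hydrophilic"]))
  # single monomer is just a placed template
  one <- make_aggregate(1, seed = 2)
  tpl <- amphiphile_template()
  expect_equal(nrow(one$atoms), nrow(tpl$atoms))
  d1 <- dist(as.matrix(one$atoms[, c("x", "y", "z")]))
  d0 <- dist(as.matrix(tpl$atoms[, c("x", "y", "z")]))
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-8)
  # impossible packing raises a packing error
  expect_error(make_aggregate(60, envelope = c(3, 2, 2), seed = 1,
                              max_retries = 20L),
               class = "packing_error")
})

test_that("aggregate principal extents track the requested envelope", {
  ext <- sapply(1:3, function(s)
    principal_extents(make_aggregate(20, envelope = c(36, 20, 20),
                                     seed = s))$extents)
  m <- rowMeans(ext)
  expect_lt(abs(m[2L] - 40) / 40, 0.10)
  expect_lt(abs(m[3L] - 40) / 40, 0.10)
  expect_lt(abs(m[1L] - 72) / 72, 0.15)  # tips shaved by orientation wobble
})

test_that("noisy curve generation matches its stated noise model", {
  m <- make_ellipsoid(15, 10, 10, 60, seed = 4)$model
  q <- seq(0.02, 0.6, length.out = 200)
  clean <- make_noisy_curve(m, q, noise_frac = 0, seed = 1)
  expect_equal(clean$intensity, debye_intensity(m, q)$intensity)
  expect_null(clean$sigma)
  n1 <- make_noisy_curve(m, q, noise_frac = 0.01, seed = 5)
  n2 <- make_noisy_curve(m, q, noise_frac = 0.01, seed = 5)
  expect_identical(n1$intensity, n2$intensity)
  # E|N(0, 0.01)| = 0.01 sqrt(2/pi) ~ 0.00798
  dev <- abs(n1$intensity / clean$intensity - 1)
  expect_equal(mean(dev), 0.01 * sqrt(2 / pi), tolerance = 0.25)
  expect_equal(n1$sigma, 0.01 * clean$intensity)
})

test_that("titration generator hits the sigmoid identities", {
  tc <- make_titration(7.2, 340, 440, pH_grid = c(2, 5, 7.2, 9, 12),
                       noise_nm = 0, seed = 1)
  expect_equal(tc$wavelength[3L], (340 + 440) / 2)  # midpoint at pH = pKa
  expect_lt(abs(tc$wavelength[1L] - 340), 1)        # acid plateau
  expect_lt(abs(tc$wavelength[5L] - 440), 1)        # base plateau
})

test_that("solvated boxes respect the exclusion distance and fill uniformly", {
  solute <- as_coordinate_set(make_ellipsoid(8, 8, 8, 50, seed = 2)$model)
  box <- make_solvated_box(solute, box_edge = 50, n_solvent = 500,
                           min_dist = 3, seed = 6)
  a <- box$atoms
  sol <- a$resname == "SOL"
  dmin <- min(as.matrix(dist(as.matrix(a[, c("x", "y", "z")])))[sol, !sol])
  expect_gte(dmin, 3)
  pure <- make_solvated_box(NULL, 50, 3000, 2.5, seed = 3)
  expect_equal(colMeans(as.matrix(pure$atoms[, c("x", "y", "z")])),
               c(25, 25, 25), tolerance = 0.05, ignore_attr = TRUE)
})
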