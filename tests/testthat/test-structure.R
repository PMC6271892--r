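test_that("radius of gyration matches closed forms and is rigid-motion invariant", {
  dumb <- bead_model(rbind(c(0, 0, 0), c(0, 0, 10)))
  expect_equal(radius_of_gyration(dumb, "uniform"), 5)
  ell <- make_ellipsoid(37.5, 21, 21, 20000L, seed = 13)
  expect_equal(radius_of_gyration(ell$model, "uniform"), ell$truth$rg,
               tolerance = 0.025)
  pos <- ell$model$positions[1:500, ]
  th <- 1.1
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  moved <- sweep(pos %*% t(R), 2L, c(100, -50, 7), `+`)
  expect_equal(radius_of_gyration(moved), radius_of_gyration(pos),
               tolerance = 1e-10)
  expect_error(radius_of_gyration(matrix(0, 1, 3)),
               class = "invariant_violation")
})

test_that("mass weighting drops unknown-element atoms", {
  df <- data.frame(name = c("C1", "C2", "XX"), resname = "LIG", resid = 1,
                   element = c("C", "C", "ZZ"),
                   x = c(0, 10, 500), y = 0, z = 0)
  cs <- suppressWarnings(coordinate_set(df))
  expect_equal(radius_of_gyration(cs, "mass"), 5)      # outlier has mass 0
  expect_gt(radius_of_gyration(cs, "uniform"), 100)
})

test_that("principal extents reproduce axis-aligned box dimensions", {
  box_corners <- function(a, b, c) as.matrix(expand.grid(
    x = c(-a, a) / 2, y = c(-b, b) / 2, z = c(-c, c) / 2))
  g <- principal_extents(box_corners(54.3, 36.8, 36.8))
  expect_equal(g$height, 54.3, tolerance = 1e-9)
  expect_equal(g$width, 36.8, tolerance = 1e-9)
  expect_equal(round(g$axial_ratio, 1), 1.5)
  g2 <- principal_extents(box_corners(72.0, 39.2, 39.2))
  expect_equal(round(g2$axial_ratio, 1), 1.8)
  # rotations leave a generic cloud's descriptors unchanged
  cloud <- make_ellipsoid(30, 17, 11, 400, seed = 8)$model$positions
  th <- 0.6
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  g3 <- principal_extents(cloud)
  g4 <- principal_extents(sweep(cloud %*% t(R), 2L, c(3, 4, 5), `+`))
  expect_equal(g4$extents, g3$extents, tolerance = 1e-8)
  expect_error(principal_extents(cbind(1:9, 2 * (1:9), 3 * (1:9))),
               class = "degenerate_configuration")
})

test_that("g(r) of an ideal gas is one and excluded shells show as zeros", {
  box <- make_solvated_box(NULL, box_edge = 40, n_solvent = 40000L,
                           min_dist = 0, seed = 17)
  a <- box$atoms
  center <- which.min((a$x - 20)^2 + (a$y - 20)^2 + (a$z - 20)^2)
  prof <- rdf(box, reference = center, target = setdiff(seq_len(nrow(a)), center),
              r_max = 12, bin_width = 0.5)
  beyond <- prof$r > 3
  expect_lt(max(abs(prof$g[beyond] - 1)), 0.35)     # per-bin Poisson noise
  expect_lt(abs(mean(prof$g[beyond]) - 1), 0.05)
  # excluded shell around a solute
  solute <- coordinate_set(data.frame(name = "C", resname = "LIG", resid = 1,
                                      element = "C", x = 0, y = 0, z = 0))
  sbox <- make_solvated_box(solute, 40, 20000L, min_dist = 4, seed = 18)
  sa <- sbox$atoms
  p2 <- rdf(sbox, reference = which(sa$resname == "LIG"),
            target = which(sa$resname == "SOL"), r_max = 12, bin_width = 0.5)
  expect_equal(max(p2$g[p2$r < 3.5]), 0)
  expect_gt(mean(p2$g[p2$r > 6]), 0.8)
  expect_error(rdf(sbox, reference = 1, target = 1, r_max = 5),
               class = "selection_error")
})

test_that("buried tails see less solvent than surface heads", {
  agg <- make_aggregate(20, seed = 5)
  box <- make_solvated_box(agg, box_edge = 90, n_solvent = 25000L,
                           min_dist = 2.5, seed = 6)
  a <- box$atoms
  g_tail <- rdf(box, reference = which(a$part %in% "hydrophobic"),
                target = which(a$resname == "SOL"), r_max = 8, bin_width = 0.5)
  g_head <- rdf(box, reference = which(a$part %in% "hydrophilic"),
                target = which(a$resname == "SOL"), r_max = 8, bin_width = 0.5)
  shell <- g_tail$r >= 2.5 & g_tail$r <= 6
  expect_lt(mean(g_tail$g[shell]), mean(g_head$g[shell]))
})

test_that("Shrake-Rupley SASA matches closed forms and occlusion limits", {
  one <- coordinate_set(data.frame(name = "C", resname = "X", resid = 1,
                                   element = "C", x = 0, y = 0, z = 0))
  s1 <- sasa(one, probe = 1.4)
  expect_equal(s1$area, 4 * pi * 3.1^2, tolerance = 1e-9)  # every point free
  expect_equal(s1$area_nm2, s1$area / 100)
  two <- coordinate_set(data.frame(name = c("C", "O"), resname = "X",
                                   resid = 1:2, element = c("C", "O"),
                                   x = c(0, 500), y = 0, z = 0))
  s2 <- sasa(two, probe = 1.4)
  expect_equal(s2$area, 4 * pi * (3.1^2 + 2.92^2), tolerance = 1e-9)
  # fully caged atom contributes nothing
  cage_pts <- 3.0 * micellometry:::golden_sphere_points(120L)
  cage <- coordinate_set(data.frame(
    name = "C", resname = "CAG", resid = seq_len(121L), element = "C",
    x = c(0, cage_pts[, 1L]), y = c(0, cage_pts[, 2L]), z = c(0, cage_pts[, 3L])))
  expect_equal(sasa(cage, probe = 1.4)$per_atom[1L], 0)
  # adding neighbours never increases an atom's exposed area
  base <- data.frame(name = "C", resname = "X", resid = 1, element = "C",
                     x = 0, y = 0, z = 0)
  prev <- Inf
  for (k in 1:4) {
    nb <- data.frame(name = "C", resname = "X", resid = 1 + seq_len(k),
                     element = "C", x = 3 * seq_len(k), y = 0, z = 0)
    cur <- sasa(coordinate_set(rbind(base, nb)))$per_atom[1L]
    expect_lte(cur, prev + 1e-9)
    prev <- cur
  }
  unknown <- coordinate_set(data.frame(name = "Q", resname = "X", resid = 1,
                                       element = "C", x = 0, y = 0, z = 0))
  unknown$atoms$element <- "QQ"
  expect_error(sasa(unknown), class = "unknown_element")
})

test_that("dihedral angles follow the IUPAC sign convention", {
  mk <- function(p4) coordinate_set(data.frame(
    name = c("A1", "A2", "A3", "A4"), resname = "X", resid = 1:4,
    element = "C",
    x = c(0, 0, 1, p4[1]), y = c(1, 0, 0, p4[2]), z = c(0, 0, 0, p4[3])))
  nm <- c("A1", "A2", "A3", "A4"); rs <- 1:4
  expect_equal(dihedral(mk(c(1, -1, 0)), nm, rs), 180)
  expect_equal(dihedral(mk(c(1, 1, 0)), nm, rs), 0)
  plus <- dihedral(mk(c(1, cos(1), sin(1))), nm, rs)
  minus <- dihedral(mk(c(1, cos(1), -sin(1))), nm, rs)
  expect_equal(plus, -minus, tolerance = 1e-10)   # mirror negates the angle
  expect_gt(abs(plus), 1)                         # and it is non-planar
  colin <- coordinate_set(data.frame(
    name = c("A1", "A2", "A3", "A4"), resname = "X", resid = 1:4,
    element = "C", x = 0:3, y = 0, z = 0))
  expect_error(dihedral(colin, nm, rs), class = "undefined_angle")
})

test_that("logarithmic growth trends fit exactly and match the printed series", {
  n <- c(2, 4, 8, 16)
  g <- growth_trend(n, 3 + 2 * log(n))
  expect_equal(g$a, 3, tolerance = 1e-10)
  expect_equal(g$b, 2, tolerance = 1e-10)
  expect_equal(g$R, 1, tolerance = 1e-10)
  # micelle Rg growth series (2,3,4,10,20 monomers): high correlation
  rg <- growth_trend(c(2, 3, 4, 10, 20), c(8.8, 10.0, 10.8, 15.7, 22.0))
  expect_equal(rg$R, 0.9801, tolerance = 1e-3)  # computed reference value
  expect_gt(rg$R, 0.95)
  flat <- growth_trend(c(2, 5, 9), c(4, 4, 4))
  expect_equal(flat$b, 0, tolerance = 1e-12)
  expect_error(growth_trend(c(2, 2, 2), c(1, 2, 3)),
               class = "invariant_violation")
})
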