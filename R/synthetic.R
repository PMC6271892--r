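## Seeded synthetic-data generators: every input the pipeline needs, with
## known ground truth, so all downstream stages are testable without
## external data.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Uniform bead ellipsoid with ground truth
#'
#' Fills the ellipsoid \eqn{x^2/a^2 + y^2/b^2 + z^2/c^2 \le 1} with beads by
#' rejection sampling from the bounding box (unit weights).  The returned
#' ground truth carries the closed forms for a uniform ellipsoid:
#' \eqn{D_{max} = 2a}, \eqn{R_g = \sqrt{(a^2+b^2+c^2)/5}}, axial ratio
#' \eqn{a/b}.  Rejection (not lattice) filling avoids lattice artifacts in
#' the distance spectrum.
#'
#' @param a,b,c Semi-axes in Angstrom, `a >= b >= c > 0`.
#' @param n_beads Number of beads (>= 10).
#' @param seed Integer seed (reproducibility contract).
#' @return A list with elements `model` ([bead_model()]) and `truth`
#'   ([ground_truth()]).
#' @examples
#' e <- make_ellipsoid(37.5, 21, 21, n_beads = 500, seed = 1)
#' e$truth
#' @export
make_ellipsoid <- function(a, b, c, n_beads = 5000L, seed = NULL) {
  if (!(a >= b && b >= c && c > 0))
    stop_micello("invariant_violation", "need a >= b >= c > 0")
  if (n_beads < 10L)
    stop_micello("insufficient_sampling", "n_beads must be >= 10")
  pos <- with_seed(seed, {
    out <- matrix(0, 0L, 3L)
    while (nrow(out) < n_beads) {
      m <- ceiling((n_beads - nrow(out)) / 0.5)  # ellipsoid fills pi/6 of box
      cand <- cbind(runif(m, -a, a), runif(m, -b, b), runif(m, -c, c))
      keep <- (cand[, 1L] / a)^2 + (cand[, 2L] / b)^2 + (cand[, 3L] / c)^2 <= 1
      out <- rbind(out, cand[keep, , drop = FALSE])
    }
    out[seq_len(n_beads), , drop = FALSE]
  })
  shape <- if (a == b && b == c) "sphere" else "prolate"
  list(model = bead_model(pos, label = sprintf("ellipsoid %g/%g/%g", a, b, c)),
       truth = ground_truth(shape, c(a, b, c), dmax = 2 * a,
                            rg = sqrt((a^2 + b^2 + c^2) / 5),
                            axial_ratio = a / b))
}

#' Core-shell bead sphere
#'
#' Beads uniformly fill the sphere of radius `r_shell`; those inside
#' `r_core` carry weight `w_core`, the rest `w_shell`.  Negative weights
#' model inverted core contrast.
#'
#' @param r_core,r_shell Radii in Angstrom, `0 < r_core < r_shell`.
#' @param w_core,w_shell Scattering weights.
#' @param n_beads Number of beads.
#' @param seed Integer seed.
#' @return A [bead_model()].
#' @export
make_core_shell_sphere <- function(r_core, r_shell, w_core = 1, w_shell = 1,
                                   n_beads = 5000L, seed = NULL) {
  if (!(r_core > 0 && r_core < r_shell))
    stop_micello("geometry_error", "need 0 < r_core < r_shell")
  if (!all(is.finite(c(w_core, w_shell))))
    stop_micello("invariant_violation", "weights must be finite")
  e <- make_ellipsoid(r_shell, r_shell, r_shell, n_beads, seed)
  r <- sqrt(rowSums(e$model$positions^2))
  w <- ifelse(r <= r_core, w_core, w_shell)
  if (all(w == 0)) w[1L] <- .Machine$double.eps  # degenerate all-zero contrast
  bead_model(e$model$positions, w, label = sprintf("core-shell %g/%g", r_core, r_shell))
}

#' Schematic amphiphile template
#'
#' A minimal coarse bead amphiphile: three hydrophobic tail beads (carbon)
#' and two hydrophilic head beads (oxygen) along +z at `spacing` Angstrom.
#' A schematic — not a reconstruction of any particular surfactant — whose
#' only purpose is to give aggregates a head/tail contrast that solvation
#' descriptors can detect.  The `part` column labels each atom
#' `"hydrophobic"` or `"hydrophilic"`.
#'
#' @param spacing Bead spacing in Angstrom.
#' @return A [coordinate_set()] with a `part` column.
#' @export
amphiphile_template <- function(spacing = 3) {
  z <- spacing * (0:4)
  coordinate_set(data.frame(
    name = c("TL1", "TL2", "TL3", "HD1", "HD2"),
    resname = "AMP", resid = 1L,
    element = c("C", "C", "C", "O", "O"),
    x = 0, y = 0, z = z,
    part = c(rep("hydrophobic", 3L), rep("hydrophilic", 2L)),
    group = 1L, stringsAsFactors = FALSE))
}

random_rotation <- function() {
  ## uniform random rotation via normalized quaternion
  qv <- rnorm(4L); qv <- qv / sqrt(sum(qv^2))
  w <- qv[1L]; x <- qv[2L]; y <- qv[3L]; z <- qv[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

## rotation taking unit vector u onto unit vector v
rotation_onto <- function(u, v) {
  axis <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(axis^2)); cth <- sum(u * v)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- p - sum(p * u) * u; axis <- axis / sqrt(sum(axis^2))
    K <- rbind(c(0, -axis[3], axis[2]), c(axis[3], 0, -axis[1]),
               c(-axis[2], axis[1], 0))
    return(diag(3) + 2 * K %*% K)
  }
  axis <- axis / s
  K <- rbind(c(0, -axis[3], axis[2]), c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  diag(3) + s * K + (1 - cth) * K %*% K
}

#' Amphiphile aggregate (schematic micelle)
#'
#' Places `n_monomers` randomly rotated copies of a small amphiphile
#' template inside a prolate envelope, with tails biased (not forced)
#' toward the aggregate center: each monomer's tail-to-head axis is aligned
#' outward along its radial direction and then perturbed by a random wobble,
#' so solvation descriptors see buried tails without hand-tuned geometry.
#' Placements closer than `min_sep` to any placed atom are resampled; a
#' packing error is raised after bounded retries.
#'
#' @param n_monomers Number of monomers (>= 1).
#' @param template A [coordinate_set()] with a `part` column containing
#'   both `"hydrophobic"` and `"hydrophilic"` atoms.
#' @param envelope Semi-axes (a, b, c) of the placement envelope, Angstrom.
#'   Default grows as n^(1/3) with axial ratio 1.8.
#' @param min_sep Minimum inter-atom separation, Angstrom.
#' @param seed Integer seed.
#' @param max_retries Per-monomer placement retries before failing.
#' @return A [coordinate_set()] (atoms keep the template's `part` labels;
#'   `group` numbers the monomers).
#' @export
make_aggregate <- function(n_monomers, template = amphiphile_template(),
                           envelope = NULL, min_sep = 1.5, seed = NULL,
                           max_retries = 400L) {
  if (n_monomers < 1L)
    stop_micello("invariant_violation", "n_monomers must be >= 1")
  if (is.null(template$atoms$part) ||
      length(intersect(c("hydrophobic", "hydrophilic"),
                       unique(template$atoms$part))) < 2L)
    stop_micello("invariant_violation",
                 "template must label both hydrophobic and hydrophilic parts")
  if (is.null(envelope)) {
    b <- 7 * n_monomers^(1 / 3)
    envelope <- c(1.8 * b, b, b)
  }
  tpl <- template$atoms
  tpos0 <- as.matrix(tpl[, c("x", "y", "z")])
  tpos0 <- sweep(tpos0, 2L, colMeans(tpos0))
  tail_c <- colMeans(tpos0[tpl$part == "hydrophobic", , drop = FALSE])
  head_c <- colMeans(tpos0[tpl$part == "hydrophilic", , drop = FALSE])
  axis0 <- head_c - tail_c
  axis0 <- axis0 / sqrt(sum(axis0^2))  # tail -> head direction in template
  ## head-group centroid sits (with jitter) on the envelope surface, tails
  ## inward: a monolayer shell, the way amphiphiles tile a micelle rim.
  ## Directions are quasi-uniform (golden-section set, poles on the major
  ## axis, angular jitter): purely random directions leave the envelope
  ## tips statistically empty at small n.
  head_offset <- sum(head_c * axis0)
  base_dirs <- golden_sphere_points(n_monomers)[, c(3L, 1L, 2L), drop = FALSE]
  if (n_monomers > 1L) {  # stretch so the first/last directions hit the poles
    base_dirs[, 1L] <- base_dirs[, 1L] / (1 - 1 / n_monomers)
    base_dirs <- base_dirs / sqrt(rowSums(base_dirs^2))
  }
  with_seed(seed, {
    placed <- NULL
    rows <- vector("list", n_monomers)
    for (k in seq_len(n_monomers)) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        ## micelle-like shell placement: uniform direction, radial fraction
        ## biased toward the envelope surface, tails pointing inward
        dir <- base_dirs[k, ] + (0.05 + 0.1 * (try - 1L)) * rnorm(3L)
        dir <- dir / sqrt(sum(dir^2))
        surfp <- dir / sqrt(sum((dir / envelope)^2)) * runif(1L, 0.98, 1)
        outward <- surfp / sqrt(sum(surfp^2))
        center <- surfp - outward * head_offset
        ## align tail->head with outward (tails buried), then wobble
        wob <- 0.35  # wobble keeps burial a bias, not a rule
        target <- outward + wob * rnorm(3L)
        target <- target / sqrt(sum(target^2))
        pos <- tpos0 %*% t(rotation_onto(axis0, target))
        pos <- sweep(pos, 2L, center, `+`)
        if (is.null(placed) ||
            min_cross_dist_cpp(pos, placed, min_sep) >= min_sep) {
          placed <- rbind(placed, pos)
          rows[[k]] <- pos
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop_micello("packing_error",
                     "could not place monomer %d without clash after %d retries",
                     k, max_retries)
    }
    atoms <- do.call(rbind, lapply(seq_len(n_monomers), function(k) {
      data.frame(name = tpl$name, resname = tpl$resname, resid = k,
                 element = tpl$element,
                 x = rows[[k]][, 1L], y = rows[[k]][, 2L], z = rows[[k]][, 3L],
                 part = tpl$part, group = k, stringsAsFactors = FALSE)
    }))
    coordinate_set(atoms)
  })
}

#' Noisy (optionally slit-smeared) synthetic scattering curve
#'
#' Computes the Debye intensity of a bead model, optionally applies slit
#' smearing, then multiplies each point by \eqn{1 + \epsilon},
#' \eqn{\epsilon \sim N(0, \mathrm{noise\_frac})}; the stored uncertainty
#' is `noise_frac * I` (of the noiseless curve).  With `noise_frac = 0` the
#' curve is exact and carries no sigma.
#'
#' @param model A [bead_model()].
#' @param q_grid q values (default 0.02 to 0.6 by 0.004, the measured
#'   range of a Kratky camera at Cu K-alpha).
#' @param noise_frac Relative noise level (>= 0).
#' @param smear_profile Optional [slit_profile()].
#' @param seed Integer seed.
#' @return A [scattering_curve()].
#' @export
make_noisy_curve <- function(model, q_grid = seq(0.02, 0.6, by = 0.004),
                             noise_frac = 0.01, smear_profile = NULL,
                             seed = NULL) {
  if (noise_frac < 0)
    stop_micello("invariant_violation", "noise_frac must be >= 0")
  curve <- debye_intensity(model, q_grid)
  if (!is.null(smear_profile)) curve <- slit_smear(curve, smear_profile)
  if (noise_frac > 0) {
    eps <- with_seed(seed, rnorm(length(q_grid), 0, noise_frac))
    sig <- noise_frac * curve$intensity
    curve$intensity <- curve$intensity * (1 + eps)
    curve$sigma <- sig
  }
  curve$meta$noise_frac <- noise_frac
  curve
}

#' Synthetic sigmoidal titration table
#'
#' \eqn{\lambda(pH) = \lambda_A + (\lambda_B - \lambda_A) / (1 +
#' 10^{pKa - pH}) + N(0, \mathrm{noise\_nm})}: the Henderson--Hasselbalch
#' sigmoid between an acid and a base emission plateau.
#'
#' @param pKa Dissociation constant (midpoint of the transition).
#' @param lambda_acid,lambda_base Plateau wavelengths, nm.
#' @param pH_grid pH values within \[0, 14\].
#' @param noise_nm Gaussian noise sd in nm.
#' @param seed Integer seed.
#' @return A [titration_curve()].
#' @export
make_titration <- function(pKa, lambda_acid = 340, lambda_base = 440,
                           pH_grid = seq(2.4, 11.1, by = 0.5),
                           noise_nm = 0.2, seed = NULL) {
  if (any(pH_grid < 0 | pH_grid > 14))
    stop_micello("invariant_violation", "pH_grid must lie in [0, 14]")
  lam <- lambda_acid + (lambda_base - lambda_acid) / (1 + 10^(pKa - pH_grid))
  if (noise_nm > 0)
    lam <- lam + with_seed(seed, rnorm(length(pH_grid), 0, noise_nm))
  titration_curve(pH_grid, lam)
}

#' Solvated box around a solute
#'
#' Centers the solute in a cubic box of edge `box_edge` and adds
#' `n_solvent` uniformly random solvent points (resname `SOL`, oxygen),
#' rejecting any draw within `min_dist` of a solute atom; a geometric
#' stand-in for an equilibrated water box, for testing RDF/SASA machinery.
#'
#' @param solute A [coordinate_set()] or `NULL` for pure solvent.
#' @param box_edge Box edge, Angstrom.
#' @param n_solvent Number of solvent points.
#' @param min_dist Exclusion distance from solute atoms, Angstrom.
#' @param seed Integer seed.
#' @return A [coordinate_set()] with `box` set; solvent atoms have resname
#'   `"SOL"`.
#' @export
make_solvated_box <- function(solute = NULL, box_edge = 60, n_solvent = 2000L,
                              min_dist = 2.5, seed = NULL) {
  half <- box_edge / 2
  sol_atoms <- NULL
  sol_pos <- NULL
  if (!is.null(solute)) {
    a <- solute$atoms
    ctr <- colMeans(as.matrix(a[, c("x", "y", "z")]))
    a$x <- a$x - ctr[1L] + half
    a$y <- a$y - ctr[2L] + half
    a$z <- a$z - ctr[3L] + half
    sol_atoms <- a
    sol_pos <- as.matrix(a[, c("x", "y", "z")])
  }
  pts <- with_seed(seed, {
    acc <- matrix(0, 0L, 3L)
    attempts <- 0L
    while (nrow(acc) < n_solvent) {
      attempts <- attempts + 1L
      if (attempts > 200L)
        stop_micello("packing_error",
                     "could not place %d solvent points at min_dist %.2f",
                     n_solvent, min_dist)
      m <- 2L * (n_solvent - nrow(acc)) + 10L
      cand <- matrix(runif(3L * m, 0, box_edge), m, 3L)
      if (!is.null(sol_pos)) {
        keep <- vapply(seq_len(m), function(i)
          min_cross_dist_cpp(cand[i, , drop = FALSE], sol_pos, min_dist) >= min_dist,
          logical(1L))
        cand <- cand[keep, , drop = FALSE]
      }
      acc <- rbind(acc, cand)
    }
    acc[seq_len(n_solvent), , drop = FALSE]
  })
  nsol0 <- if (is.null(sol_atoms)) 0L else max(sol_atoms$group)
  water <- data.frame(name = "OW", resname = "SOL",
                      resid = nsol0 + seq_len(n_solvent), element = "O",
                      x = pts[, 1L], y = pts[, 2L], z = pts[, 3L],
                      mass = element_mass("O"),
                      group = nsol0 + seq_len(n_solvent),
                      stringsAsFactors = FALSE)
  if (!is.null(sol_atoms)) {
    common <- union(names(sol_atoms), names(water))
    for (cc in setdiff(common, names(sol_atoms))) sol_atoms[[cc]] <- NA
    for (cc in setdiff(common, names(water))) water[[cc]] <- NA
    water <- rbind(sol_atoms[common], water[common])
  }
  coordinate_set(water, box = rep(box_edge, 3L))
}
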