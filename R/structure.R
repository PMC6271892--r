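## Coordinate-space descriptors: radius of gyration, principal extents,
## g(r), Shrake-Rupley SASA, dihedral angles, logarithmic growth trends.

#' Radius of gyration of a coordinate set
#'
#' \eqn{R_g = \sqrt{\sum_i w_i |r_i - \bar r|^2 / \sum_i w_i}} about the
#' weighted centroid.  Mass weighting (the trajectory-tool convention) is
#' the default; atoms of unknown element (mass 0) then drop out.  Uniform
#' weighting suits bead models.
#'
#' @param x A [coordinate_set()], [bead_model()] or n x 3 matrix.
#' @param weighting `"mass"` or `"uniform"`.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(x, weighting = c("mass", "uniform")) {
  weighting <- match.arg(weighting)
  pos <- positions_of(x)
  if (nrow(pos) < 2L)
    stop_micello("invariant_violation", "need at least 2 atoms")
  w <- if (weighting == "mass") masses_of(x) else rep(1, nrow(pos))
  if (all(w == 0))
    stop_micello("invariant_violation", "all weights are zero")
  ctr <- colSums(pos * w) / sum(w)
  d2 <- rowSums(sweep(pos, 2L, ctr)^2)
  sqrt(sum(w * d2) / sum(w))
}

#' Principal-axis extents of a coordinate set
#'
#' Diagonalizes the (unweighted) covariance of atom positions; the height
#' is the extent (max minus min projection) along the first principal
#' axis, the width the mean of the two transverse extents, and the axial
#' ratio their quotient — the height/width convention behind tabulated
#' micelle dimensions such as 54.3/36.8 -> 1.5.
#'
#' @param x A [coordinate_set()], [bead_model()] or n x 3 matrix with at
#'   least 4 non-collinear atoms.
#' @return An object of class `micelle_geometry`: `rg`, `height`, `width`,
#'   `axial_ratio`, `extents` (all three principal extents).
#' @export
principal_extents <- function(x) {
  pos <- positions_of(x)
  if (nrow(pos) < 4L)
    stop_micello("invariant_violation", "need at least 4 atoms")
  ctr <- colMeans(pos)
  cpos <- sweep(pos, 2L, ctr)
  ev <- eigen(crossprod(cpos) / nrow(cpos), symmetric = TRUE)
  if (ev$values[2L] <= 1e-10 * max(ev$values[1L], 1e-300))
    stop_micello("degenerate_configuration", "atoms are (near-)collinear")
  ## Tied eigenvalues (e.g. a square cross-section) leave the eigenbasis
  ## arbitrary within the tied subspace; fix it deterministically by
  ## Gram-Schmidt on the coordinate axes projected into that subspace, so
  ## axis-aligned bodies report their axis-aligned extents.
  V <- ev$vectors
  tol <- 1e-8 * max(ev$values)
  i <- 1L
  while (i <= 3L) {
    j <- i
    while (j < 3L && abs(ev$values[j + 1L] - ev$values[i]) <= tol) j <- j + 1L
    if (j > i) {
      B <- V[, i:j, drop = FALSE]
      P <- B %*% t(B)
      cand <- P %*% diag(3L)
      cand <- cand[, order(-colSums(cand^2)), drop = FALSE]
      basis <- NULL
      for (k in seq_len(ncol(cand))) {
        v <- cand[, k]
        if (!is.null(basis)) v <- v - basis %*% crossprod(basis, v)
        nv <- sqrt(sum(v^2))
        if (nv > 1e-10) basis <- cbind(basis, v / nv)
        if (!is.null(basis) && ncol(basis) == j - i + 1L) break
      }
      V[, i:j] <- basis
    }
    i <- j + 1L
  }
  proj <- cpos %*% V
  extents <- apply(proj, 2L, function(v) diff(range(v)))
  extents <- sort(extents, decreasing = TRUE)
  structure(list(rg = radius_of_gyration(x, "uniform"),
                 height = extents[1L],
                 width = mean(extents[2:3]),
                 axial_ratio = extents[1L] / mean(extents[2:3]),
                 extents = extents),
            class = "micelle_geometry")
}

#' @export
print.micelle_geometry <- function(x, ...) {
  cat(sprintf("<micelle_geometry> Rg %.2f A, height %.2f A, width %.2f A, axial ratio %.2f\n",
              x$rg, x$height, x$width, x$axial_ratio))
  invisible(x)
}

#' Select atoms of a coordinate set
#'
#' Builds an integer atom index from any combination of name, residue name,
#' residue index, element or part label (values are OR-ed within a field,
#' AND-ed across fields).
#'
#' @param coords A [coordinate_set()].
#' @param name,resname,resid,element,part Optional filters.
#' @return Integer vector of atom indices.
#' @export
select_atoms <- function(coords, name = NULL, resname = NULL, resid = NULL,
                         element = NULL, part = NULL) {
  stopifnot(inherits(coords, "coordinate_set"))
  a <- coords$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(element)) keep <- keep & a$element %in% element
  if (!is.null(part)) {
    if (is.null(a$part)) stop_micello("selection_error", "no part labels present")
    keep <- keep & a$part %in% part
  }
  which(keep)
}

resolve_selection <- function(coords, sel, what) {
  idx <- if (is.numeric(sel)) as.integer(sel)
  else if (is.logical(sel)) which(sel)
  else if (is.list(sel)) do.call(select_atoms, c(list(coords), sel))
  else stop_micello("selection_error", "%s selector must be indices, a logical mask or a filter list", what)
  if (length(idx) == 0L)
    stop_micello("selection_error", "%s selection is empty", what)
  idx
}

#' Radial distribution function g(r)
#'
#' Histogram of reference-target distances normalized by the spherical
#' shell volume \eqn{4\pi r^2 \Delta r}, the target number density and the
#' reference count, so an ideal gas gives g = 1.  With a periodic box the
#' minimum-image convention is applied and the density uses the box volume;
#' without one the density is approximated by the target set's bounding
#' sphere (documented approximation for finite clusters).
#'
#' @param coords A [coordinate_set()].
#' @param reference,target Atom selectors (see [select_atoms()]); must be
#'   disjoint and non-empty.
#' @param r_max Histogram range, Angstrom.
#' @param bin_width Bin width, Angstrom.
#' @param box `NULL` (use `coords$box` if present), `FALSE` (ignore any
#'   box), or length-3 edge lengths.
#' @return An object of class `rdf_profile`: `r` (bin centers), `g`,
#'   `counts`, `density`.
#' @export
rdf <- function(coords, reference, target, r_max = 10, bin_width = 0.1,
                box = NULL) {
  stopifnot(inherits(coords, "coordinate_set"))
  iref <- resolve_selection(coords, reference, "reference")
  itgt <- resolve_selection(coords, target, "target")
  if (length(intersect(iref, itgt)))
    stop_micello("selection_error", "reference and target selections overlap")
  if (bin_width <= 0) stop_micello("invariant_violation", "bin_width must be > 0")
  pos <- positions_of(coords)
  if (is.null(box)) box <- coords$box
  if (isFALSE(box)) box <- NULL
  nbins <- ceiling(r_max / bin_width)
  counts <- rdf_hist_cpp(pos[iref, , drop = FALSE], pos[itgt, , drop = FALSE],
                         bin_width, nbins,
                         if (is.null(box)) numeric(0) else as.numeric(box))
  centers <- (seq_len(nbins) - 0.5) * bin_width
  vol <- if (!is.null(box)) prod(box) else {
    tp <- pos[itgt, , drop = FALSE]
    ctr <- colMeans(tp)
    rad <- sqrt(max(rowSums(sweep(tp, 2L, ctr)^2))) + bin_width
    4 / 3 * pi * rad^3
  }
  dens <- length(itgt) / vol
  shell <- 4 * pi * centers^2 * bin_width
  g <- counts / (length(iref) * dens * shell)
  structure(list(r = centers, g = g, counts = counts, density = dens,
                 periodic = !is.null(box)),
            class = "rdf_profile")
}

#' @export
print.rdf_profile <- function(x, ...) {
  cat(sprintf("<rdf_profile> %d bins to r = %.2f A (%s normalization)\n",
              length(x$r), max(x$r) + (x$r[2] - x$r[1]) / 2,
              if (x$periodic) "periodic box" else "bounding sphere"))
  invisible(x)
}

#' @export
plot.rdf_profile <- function(x, ...) {
  plot(x$r, x$g, type = "l", xlab = "r [Angstrom]", ylab = "g(r)", ...)
  abline(h = 1, lty = 3)
  invisible(x)
}

## Default van der Waals radii (Angstrom) for SASA.
SASA_RADII <- c(C = 1.70, O = 1.52, N = 1.55, H = 1.20, S = 1.80, P = 1.80)

## Deterministic golden-section spiral on the unit sphere.
golden_sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1L)
  z <- 1 - 2 * i / n
  rxy <- sqrt(pmax(0, 1 - z^2))
  cbind(rxy * cos(phi), rxy * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Samples each atom's solvent-accessible sphere (radius = van der Waals
#' radius + probe) at `n_points` deterministic golden-section points; the
#' accessible fraction times the sphere area is the atom's contribution.
#' The deterministic point set makes results exactly reproducible.
#'
#' @param coords A [coordinate_set()] or [bead_model()].
#' @param radii Named per-element radius overrides, Angstrom (merged over
#'   defaults C 1.70, O 1.52, N 1.55, H 1.20, S 1.80, P 1.80).
#' @param probe Probe radius, Angstrom (default 1.4, a water molecule).
#' @param n_points Sphere sample points per atom (default 960).
#' @return An object of class `sasa_result`: `area` (A^2), `area_nm2`,
#'   `per_atom` (A^2).
#' @export
sasa <- function(coords, radii = NULL, probe = 1.4, n_points = 960L) {
  if (probe < 0) stop_micello("invariant_violation", "probe must be >= 0")
  pos <- positions_of(coords)
  elements <- if (inherits(coords, "coordinate_set")) coords$atoms$element
  else rep("C", nrow(pos))
  rt <- SASA_RADII
  if (!is.null(radii)) rt[names(radii)] <- radii
  rad <- unname(rt[toupper(elements)])
  if (anyNA(rad))
    stop_micello("unknown_element",
                 "no SASA radius for element(s): %s; supply `radii`",
                 paste(unique(elements[is.na(rad)]), collapse = ", "))
  n <- nrow(pos)
  sph <- golden_sphere_points(n_points)
  rs <- rad + probe
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    ri <- rs[i]
    d <- sqrt(rowSums(sweep(pos, 2L, pos[i, ])^2))
    nb <- which(d < ri + rs & seq_len(n) != i)
    pts <- sweep(sph * ri, 2L, pos[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- rowSums(sweep(pts[acc, , drop = FALSE], 2L, pos[j, ])^2)
      acc[acc] <- dj >= rs[j]^2
    }
    per_atom[i] <- 4 * pi * ri^2 * sum(acc) / n_points
  }
  structure(list(area = sum(per_atom), area_nm2 = sum(per_atom) / 100,
                 per_atom = per_atom, probe = probe, n_points = n_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa> %.2f A^2 (%.3f nm^2), probe %.2f A, %d points/atom\n",
              x$area, x$area_nm2, x$probe, x$n_points))
  invisible(x)
}

#' Signed dihedral angle
#'
#' The torsion about the 2-3 bond of four atoms, each resolved uniquely by
#' atom name and residue index, via the standard atan2 of cross products;
#' IUPAC sign convention, degrees in (-180, 180].  Glycosidic-linkage
#' conventions for a (1->X) linkage: phi = O5-C1-O1-CX,
#' psi = C1-O1-CX-C(X-1); for a (1->28) ester, omega = O28A-C28-C17-C16.
#'
#' @param coords A [coordinate_set()].
#' @param names Character length-4 atom names.
#' @param resid Integer length-4 (or length-1, recycled) residue indices.
#' @return Angle in degrees.
#' @export
dihedral <- function(coords, names, resid) {
  stopifnot(inherits(coords, "coordinate_set"), length(names) == 4L)
  if (length(resid) == 1L) resid <- rep(resid, 4L)
  stopifnot(length(resid) == 4L)
  idx <- vapply(1:4, function(k) {
    i <- which(coords$atoms$name == names[k] & coords$atoms$resid == resid[k])
    if (length(i) == 0L)
      stop_micello("selection_error", "atom %s in residue %d not found",
                   names[k], resid[k])
    if (length(i) > 1L)
      stop_micello("selection_error", "atom %s in residue %d is not unique",
                   names[k], resid[k])
    i
  }, integer(1L))
  if (length(unique(idx)) != 4L)
    stop_micello("invariant_violation", "the four atoms must be distinct")
  p <- positions_of(coords)[idx, ]
  b1 <- p[2L, ] - p[1L, ]; b2 <- p[3L, ] - p[2L, ]; b3 <- p[4L, ] - p[3L, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop_micello("undefined_angle", "collinear atoms: dihedral undefined")
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Logarithmic growth-trend fit
#'
#' Fits `dimension = a + b * ln(n)` by least squares across aggregate
#' sizes and reports the Pearson correlation R between fitted and observed
#' values — the trend-line summary used for micelle growth curves.
#'
#' @param n Aggregate sizes (monomer counts), at least 3 distinct, all >= 1.
#' @param dimension Measured dimension at each n (Angstrom).
#' @return An object of class `growth_trend`: `a`, `b`, `R`, `fitted`.
#' @export
growth_trend <- function(n, dimension) {
  if (length(n) != length(dimension))
    stop_micello("invariant_violation", "n and dimension lengths differ")
  if (length(unique(n)) < 3L)
    stop_micello("invariant_violation", "need at least 3 distinct n values")
  if (any(n < 1))
    stop_micello("invariant_violation", "all n must be >= 1")
  fit <- lm(dimension ~ log(n))
  fv <- fitted(fit)
  R <- if (sd(fv) == 0 || sd(dimension) == 0) 1 else
    abs(stats::cor(fv, dimension))
  structure(list(a = coef(fit)[[1L]], b = coef(fit)[[2L]], R = R,
                 fitted = as.numeric(fv), n = n, dimension = dimension,
                 lm = fit),
            class = "growth_trend")
}

#' @export
print.growth_trend <- function(x, ...) {
  cat(sprintf("<growth_trend> dim = %.3f + %.3f ln(n), R = %.4f\n",
              x$a, x$b, x$R))
  invisible(x)
}
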