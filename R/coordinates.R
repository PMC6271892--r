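## CoordinateSet: atom records with positions in Angstrom, plus file IO.
## PDB files go through bio3d; GRO (GROMACS, nm) is parsed here and
## converted to Angstrom on read.

## Standard atomic masses (Da) for the elements a micelle/solvent model
## plausibly contains.  Unknown elements get mass 0 and are excluded from
## mass-weighted computations, with a warning at construction.
ELEMENT_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    P = 30.974, S = 32.06, F = 18.998, CL = 35.45,
                    NA. = 22.990, K = 39.098, MG = 24.305, CA = 40.078,
                    FE = 55.845, ZN = 65.38, BR = 79.904, I = 126.904)

element_mass <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  m <- unname(ELEMENT_MASSES[key])
  m[is.na(m)] <- 0
  m
}

## Infer an element symbol from a PDB/GRO atom name: strip digits and
## spaces, try the leading two characters against the known table, fall
## back to the first alphabetic character.
infer_element <- function(name) {
  vapply(name, function(nm) {
    s <- gsub("[^A-Za-z]", "", nm)
    if (nchar(s) == 0L) return("")
    two <- toupper(substr(s, 1L, 2L))
    two_key <- if (two == "NA") "NA." else two
    if (nchar(s) >= 2L && two_key %in% names(ELEMENT_MASSES) &&
        !(two %in% c("CA", "CD", "CE", "CG", "CB", "HA", "HB", "HD",
                     "HE", "HG", "ND", "NE", "NZ", "OD", "OE", "OG",
                     "SD", "SG", "CL")))  # side-chain style names stay 1-letter
      return(two)
    toupper(substr(s, 1L, 1L))
  }, character(1L), USE.NAMES = FALSE)
}

#' Construct a coordinate set
#'
#' Atom records (name, residue, element, position in Angstrom, mass in Da)
#' with optional orthorhombic box vectors and a grouping column
#' partitioning atoms into molecules/chains.  Atoms whose element is not in
#' the built-in mass table get mass 0 and are excluded from mass-weighted
#' computations (a warning is issued once, here).
#'
#' @param atoms A data.frame with columns `name`, `resname`, `resid`, `x`,
#'   `y`, `z` and optionally `element`, `mass`, `group` (defaults: element
#'   inferred from `name`, mass from element, group = `resid`).
#' @param box Optional length-3 numeric, box edge lengths in Angstrom.
#' @return An object of class `coordinate_set`.
#' @export
coordinate_set <- function(atoms, box = NULL) {
  req <- c("name", "resname", "resid", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop_micello("invariant_violation", "atoms lacks columns: %s",
                 paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L)
    stop_micello("empty_input", "coordinate set has no atoms")
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(pos)))
    stop_micello("invariant_violation", "positions must be finite")
  if (is.null(atoms$element) || all(atoms$element == ""))
    atoms$element <- infer_element(atoms$name)
  blank <- atoms$element == ""
  atoms$element[blank] <- infer_element(atoms$name[blank])
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  if (any(atoms$mass < 0))
    stop_micello("invariant_violation", "masses must be >= 0")
  if (any(atoms$mass == 0))
    warning(sprintf("%d atom(s) with unknown element have mass 0 and are excluded from mass-weighted computations",
                    sum(atoms$mass == 0)), call. = FALSE)
  if (is.null(atoms$group)) atoms$group <- atoms$resid
  if (anyNA(atoms$group))
    stop_micello("invariant_violation", "grouping must cover all atoms")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
      stop_micello("invariant_violation", "box must be 3 positive edge lengths")
  }
  structure(list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
                 box = box), class = "coordinate_set")
}

#' @export
print.coordinate_set <- function(x, ...) {
  cat(sprintf("<coordinate_set> %d atoms, %d group(s)%s\n",
              nrow(x$atoms), length(unique(x$atoms$group)),
              if (is.null(x$box)) "" else
                sprintf(", box %.1f x %.1f x %.1f A", x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

positions_of <- function(x) {
  if (inherits(x, "coordinate_set")) return(as.matrix(x$atoms[, c("x", "y", "z")]))
  if (inherits(x, "bead_model")) return(x$positions)
  if (is.matrix(x) && ncol(x) == 3L) return(x)
  stop_micello("invariant_violation", "cannot extract positions from class '%s'",
               class(x)[1L])
}

masses_of <- function(x) {
  if (inherits(x, "coordinate_set")) return(x$atoms$mass)
  rep(1, nrow(positions_of(x)))
}

#' Convert a bead model to a coordinate set
#'
#' Beads become carbon pseudo-atoms (resname `BEA`), one residue per bead,
#' so bead models can be written as PDB/GRO and fed to coordinate-space
#' descriptors.
#'
#' @param model A [bead_model()].
#' @return A [coordinate_set()].
#' @export
as_coordinate_set <- function(model) {
  stopifnot(inherits(model, "bead_model"))
  n <- nrow(model$positions)
  coordinate_set(data.frame(name = "C", resname = "BEA", resid = seq_len(n),
                            element = "C",
                            x = model$positions[, 1L],
                            y = model$positions[, 2L],
                            z = model$positions[, 3L]))
}

## ---- file IO ---------------------------------------------------------------

#' Read molecular coordinates (PDB or GRO)
#'
#' Dispatches on the file extension.  PDB `ATOM`/`HETATM` records are read
#' with the fixed-column conventions (via bio3d); GRO coordinates are in nm
#' and are converted to Angstrom.  Elements missing from the file are
#' inferred from atom names; masses come from a standard element table.
#'
#' @param path Path ending in `.pdb` or `.gro`.
#' @return A [coordinate_set()].
#' @export
read_coordinates <- function(path) {
  if (!file.exists(path)) stop_micello("io_error", "file not found: '%s'", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pdb = read_pdb_file(path),
         gro = read_gro_file(path),
         stop_micello("format_error",
                      "unrecognized coordinate extension '.%s' (expect .pdb or .gro)",
                      ext))
}

read_pdb_file <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop_micello("parse_error", "PDB parse failure in '%s': %s",
                                 path, conditionMessage(e)))
  a <- pdb$atom
  if (nrow(a) == 0L) stop_micello("empty_input", "no ATOM/HETATM records in '%s'", path)
  elem <- a$elesy
  if (is.null(elem)) elem <- rep("", nrow(a))
  elem[is.na(elem)] <- ""
  coordinate_set(data.frame(name = trimws(a$elety), resname = trimws(a$resid),
                            resid = a$resno, element = trimws(elem),
                            x = a$x, y = a$y, z = a$z,
                            group = a$resno,
                            stringsAsFactors = FALSE))
}

read_gro_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L)
    stop_micello("parse_error", "GRO file '%s' too short", path)
  n <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(n) || length(lines) < n + 3L)
    stop_micello("parse_error", "bad atom count in GRO file '%s'", path)
  body <- lines[3:(n + 2L)]
  fixed <- function(s, a, b) substr(s, a, b)
  num <- function(s, what, i) {
    v <- suppressWarnings(as.numeric(s))
    if (anyNA(v))
      stop_micello("parse_error", "truncated or malformed GRO line %d in '%s' (%s)",
                   i[which(is.na(v))[1L]] + 2L, path, what)
    v
  }
  if (any(nchar(body) < 44L))
    stop_micello("parse_error", "truncated fixed-width GRO line %d in '%s'",
                 which(nchar(body) < 44L)[1L] + 2L, path)
  idx <- seq_along(body)
  resid <- as.integer(num(fixed(body, 1, 5), "resid", idx))
  resname <- trimws(fixed(body, 6, 10))
  name <- trimws(fixed(body, 11, 15))
  x <- num(fixed(body, 21, 28), "x", idx) * 10  # nm -> Angstrom
  y <- num(fixed(body, 29, 36), "y", idx) * 10
  z <- num(fixed(body, 37, 44), "z", idx) * 10
  boxline <- trimws(lines[n + 3L])
  box <- suppressWarnings(as.numeric(strsplit(boxline, "\\s+")[[1L]]))[1:3] * 10
  if (anyNA(box) || any(box <= 0)) box <- NULL
  coordinate_set(data.frame(name = name, resname = resname, resid = resid,
                            x = x, y = y, z = z, group = resid,
                            stringsAsFactors = FALSE),
                 box = box)
}

#' Write molecular coordinates (PDB or GRO)
#'
#' Format chosen by extension; GRO output is converted to nm.
#'
#' @param coords A [coordinate_set()] (or [bead_model()], converted).
#' @param path Path ending in `.pdb` or `.gro`.
#' @return `path`, invisibly.
#' @export
write_coordinates <- function(coords, path) {
  if (inherits(coords, "bead_model")) coords <- as_coordinate_set(coords)
  stopifnot(inherits(coords, "coordinate_set"))
  ext <- tolower(tools::file_ext(path))
  a <- coords$atoms
  if (ext == "pdb") {
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     resno = a$resid, resid = a$resname,
                     eleno = seq_len(nrow(a)), elety = a$name,
                     elesy = a$element)
  } else if (ext == "gro") {
    box <- if (is.null(coords$box)) rep(max(abs(as.matrix(a[, c("x","y","z")]))) * 2 + 10,
                                        3L) else coords$box
    lines <- c("written by micellometry", sprintf("%5d", nrow(a)),
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       a$resid %% 100000L, substr(a$resname, 1, 5),
                       substr(a$name, 1, 5), seq_len(nrow(a)) %% 100000L,
                       a$x / 10, a$y / 10, a$z / 10),
               sprintf("%10.5f%10.5f%10.5f", box[1] / 10, box[2] / 10, box[3] / 10))
    writeLines(lines, path)
  } else {
    stop_micello("format_error", "unrecognized coordinate extension '.%s'", ext)
  }
  invisible(path)
}
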