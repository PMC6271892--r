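## ScatteringCurve: a 1D SAXS intensity profile on a q grid.

#' Construct a scattering curve
#'
#' A `scattering_curve` holds a one-dimensional small-angle scattering
#' profile: the scattering vector \eqn{q = 4\pi \sin\theta / \lambda}
#' (\eqn{2\theta} the scattering angle, \eqn{\lambda} the wavelength) in
#' 1/Angstrom, the intensity in absolute units (1/cm) where calibrated, an
#' optional per-point uncertainty, and a flag recording whether the profile
#' is slit-smeared.
#'
#' @param q Numeric vector of scattering-vector values, 1/Angstrom.
#'   Must be positive, finite and strictly increasing.
#' @param intensity Numeric vector of intensities, same length as `q`.
#' @param sigma Optional numeric vector of 1-sigma uncertainties in the same
#'   units as `intensity`; `NULL` means unweighted.
#' @param smeared Logical flag: is the curve slit-smeared?
#' @param meta Named list of metadata (e.g. `wavelength` in Angstrom,
#'   `label`, `concentration` in wt%).
#' @return An object of class `scattering_curve`.
#' @examples
#' sc <- scattering_curve(q = c(0.02, 0.03), intensity = c(5.1, 4.9))
#' sc
#' @export
scattering_curve <- function(q, intensity, sigma = NULL, smeared = FALSE,
                             meta = list()) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) == 0L)
    stop_micello("empty_input", "scattering curve has no points")
  if (length(q) != length(intensity))
    stop_micello("invariant_violation", "q and intensity lengths differ (%d vs %d)",
                 length(q), length(intensity))
  if (any(!is.finite(q)) || any(q <= 0))
    stop_micello("invariant_violation", "q must be finite and > 0 everywhere")
  if (any(diff(q) <= 0))
    stop_micello("invariant_violation", "q must be strictly increasing")
  if (any(!is.finite(intensity)))
    stop_micello("invariant_violation", "intensity must be finite")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q))
      stop_micello("invariant_violation", "sigma length differs from q")
    if (any(!is.finite(sigma)) || any(sigma < 0))
      stop_micello("invariant_violation", "sigma must be finite and >= 0")
  }
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 smeared = isTRUE(smeared), meta = meta),
            class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("<scattering_curve> %d points, q in [%.4g, %.4g] 1/A%s%s\n",
              length(x$q), min(x$q), max(x$q),
              if (x$smeared) ", slit-smeared" else "",
              if (is.null(x$sigma)) "" else ", with uncertainties"))
  if (!is.null(x$meta$label)) cat("  label:", x$meta$label, "\n")
  invisible(x)
}

#' @export
plot.scattering_curve <- function(x, ..., log = "xy") {
  ok <- x$intensity > 0 | log == ""
  plot(x$q[ok], x$intensity[ok], log = log, xlab = "q [1/Angstrom]",
       ylab = "I(q)", type = "l", ...)
  invisible(x)
}

#' @export
as.data.frame.scattering_curve <- function(x, ...) {
  d <- data.frame(q = x$q, intensity = x$intensity)
  if (!is.null(x$sigma)) d$sigma <- x$sigma
  d
}

## ---- text IO ---------------------------------------------------------------

parse_numeric_table <- function(path, min_cols, max_cols, what) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*($|#|;)", lines))
  if (length(keep) == 0L)
    stop_micello("empty_input", "%s: no data rows in '%s'", what, path)
  rows <- lapply(keep, function(i) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(toks))
    if (length(vals) < min_cols || length(vals) > max_cols || anyNA(vals))
      stop_micello("parse_error", "%s: malformed row at line %d of '%s': \"%s\"",
                   what, i, path, lines[i])
    vals
  })
  ncols <- vapply(rows, length, 1L)
  if (length(unique(ncols)) != 1L)
    stop_micello("parse_error", "%s: inconsistent column count in '%s'", what, path)
  list(mat = do.call(rbind, rows),
       header = lines[grepl("^\\s*[#;]", lines)])
}

#' Read a scattering curve from whitespace-delimited text
#'
#' Accepts two-column (`q I`), three-column (`q I sigma`) and
#' header-annotated files (the same columns preceded by `#` comment lines,
#' which may carry `key: value` metadata such as `label`, `wavelength`,
#' `smeared`).  Lines starting with `#` or `;` are skipped.
#'
#' @param path Path to the file.
#' @param dialect One of `"auto"`, `"two-column"`, `"three-column"`,
#'   `"header-annotated"`.  `"auto"` infers from the column count.
#' @return A [scattering_curve()].
#' @export
read_curve <- function(path, dialect = c("auto", "two-column", "three-column",
                                         "header-annotated")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop_micello("io_error", "file not found: '%s'", path)
  tab <- parse_numeric_table(path, 2L, 3L, "scattering curve")
  m <- tab$mat
  if (dialect == "two-column" && ncol(m) != 2L)
    stop_micello("parse_error", "expected 2 columns in '%s', found %d", path, ncol(m))
  if (dialect == "three-column" && ncol(m) != 3L)
    stop_micello("parse_error", "expected 3 columns in '%s', found %d", path, ncol(m))
  meta <- list(); smeared <- FALSE
  for (h in tab$header) {
    kv <- regmatches(h, regexec("^\\s*[#;]\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", h))[[1L]]
    if (length(kv) == 3L) {
      key <- tolower(kv[2L]); val <- trimws(kv[3L])
      if (key == "smeared") smeared <- tolower(val) %in% c("true", "yes", "1")
      else {
        num <- suppressWarnings(as.numeric(val))
        meta[[key]] <- if (is.na(num)) val else num
      }
    }
  }
  scattering_curve(q = m[, 1L], intensity = m[, 2L],
                   sigma = if (ncol(m) == 3L) m[, 3L] else NULL,
                   smeared = smeared, meta = meta)
}

#' Write a scattering curve as annotated text
#'
#' Writes `q I [sigma]` columns with a `#` header carrying the units and any
#' scalar/character metadata, in a form [read_curve()] round-trips.
#'
#' @param curve A [scattering_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "scattering_curve"))
  hdr <- c("# columns: q [1/Angstrom]  I [1/cm]" ,
           sprintf("# smeared: %s", curve$smeared))
  for (key in names(curve$meta)) {
    v <- curve$meta[[key]]
    if (length(v) == 1L && (is.numeric(v) || is.character(v) || is.logical(v)))
      hdr <- c(hdr, sprintf("# %s: %s", key, format(v, digits = 10)))
  }
  m <- cbind(curve$q, curve$intensity)
  if (!is.null(curve$sigma)) m <- cbind(m, curve$sigma)
  body <- apply(m, 1L, function(r) paste(formatC(r, digits = 8, format = "g"),
                                         collapse = "  "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

## ---- TitrationCurve --------------------------------------------------------

#' Construct a titration curve
#'
#' Pairs of solution pH and the fluorescence emission-maximum wavelength
#' (nm) observed at that pH; the raw material for [hh_fit()].
#'
#' @param pH Numeric vector in \[0, 14\], strictly increasing.
#' @param wavelength Emission wavelength in nm, same length.
#' @return An object of class `titration_curve`.
#' @export
titration_curve <- function(pH, wavelength) {
  pH <- as.numeric(pH); wavelength <- as.numeric(wavelength)
  if (length(pH) != length(wavelength))
    stop_micello("invariant_violation", "pH and wavelength lengths differ")
  if (any(!is.finite(pH)) || any(pH < 0) || any(pH > 14))
    stop_micello("invariant_violation", "pH must lie in [0, 14]")
  if (any(diff(pH) <= 0))
    stop_micello("invariant_violation", "pH must be strictly increasing")
  if (any(!is.finite(wavelength)))
    stop_micello("invariant_violation", "wavelength must be finite")
  structure(list(pH = pH, wavelength = wavelength), class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("<titration_curve> %d points, pH %.2f-%.2f, lambda %.1f-%.1f nm\n",
              length(x$pH), min(x$pH), max(x$pH),
              min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' Read / write titration tables
#'
#' Two whitespace-delimited columns: pH, emission wavelength (nm); `#`/`;`
#' comments skipped.
#'
#' @param path File path.
#' @return [titration_curve()] for the reader; `path` invisibly for the writer.
#' @export
read_titration <- function(path) {
  if (!file.exists(path)) stop_micello("io_error", "file not found: '%s'", path)
  tab <- parse_numeric_table(path, 2L, 2L, "titration table")
  titration_curve(tab$mat[, 1L], tab$mat[, 2L])
}

#' @rdname read_titration
#' @param curve A [titration_curve()].
#' @export
write_titration <- function(curve, path) {
  stopifnot(inherits(curve, "titration_curve"))
  writeLines(c("# columns: pH  wavelength [nm]",
               paste(formatC(curve$pH, digits = 8, format = "g"),
                     formatC(curve$wavelength, digits = 8, format = "g"),
                     sep = "  ")), path)
  invisible(path)
}

## ---- run configs -----------------------------------------------------------

#' Read / write pipeline run configurations (YAML)
#'
#' @param path File path.
#' @return A named list for the reader; `path` invisibly for the writer.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_micello("io_error", "file not found: '%s'", path)
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config A named list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
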