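## Orchestration: run the whole workflow (simulate -> [desmear] -> ift ->
## shape -> compare, and/or titrate) from one config, with seeded
## reproducibility and a provenance manifest.

#' Per-stage seed derived from a global seed
#'
#' Stable fan-out: hashes the stage name so inserting a stage does not
#' scramble the randomness of the others.  Result is a valid 32-bit seed.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 2654435761)
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

pipeline_profile <- function(p) {
  if (is.null(p)) return(NULL)
  if (identical(p, "delta")) return(slit_profile("delta"))
  slit_profile("trapezoid", t1 = p$t1 %||% 0.05, t_max = p$t_max %||% 0.2)
}

#' Run the characterization pipeline
#'
#' Executes the configured stages in order, carrying intermediate results
#' in memory and writing per-stage artifacts plus a provenance manifest
#' (`manifest.yaml`: inputs, parameters, output files with MD5 checksums,
#' seeds).  Reruns with the same config and seed are bit-identical.
#' Recognized stages:
#'
#' * `simulate` — build a synthetic particle (`shape`:
#'   sphere/prolate/coreshell/aggregate, `dims`, `n_beads`) and its noisy,
#'   optionally slit-smeared curve (`noise`, `smeared`, `profile`).
#' * `desmear` — undo slit smearing of the current curve.
#' * `ift` — indirect Fourier transform of the current curve (`dmax` or
#'   `scan` = list(from, to, by), `n_basis`, `lambda`, `q_min_cut`).
#' * `shape` — shape descriptors from the fitted p(r).
#' * `compare` — model-vs-scattering comparison: coordinate-space
#'   descriptors of the simulated beads against the p(r)-derived ones, and
#'   the scale/chi match of the model curve to the data.
#' * `titrate` — synthesize (`pKa`, `noise_nm`, ...) and fit a titration
#'   curve.
#'
#' A stage failure aborts with the failing stage named; artifacts already
#' written are retained.
#'
#' @param config Named list or path to a YAML file (see
#'   `system.file("extdata", "demo_run.yaml", package = "micellometry")`).
#' @param outdir Output directory (default from config, else tempdir).
#' @return The manifest, invisibly (also written as YAML).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (!is.list(config)) stop_micello("config_error", "config must be a list or path")
  stages <- config$stages %||% character(0)
  seed <- config$seed %||% 1L
  outdir <- outdir %||% config$outdir %||% tempfile("micellometry_run_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  known <- c("simulate", "desmear", "ift", "shape", "compare", "titrate")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop_micello("config_error", "unknown stage(s): %s", paste(bad, collapse = ", "))
  state <- new.env(parent = emptyenv())
  manifest <- list(seed = seed, stages = list())
  for (st in stages) {
    res <- tryCatch(
      pipeline_stage(st, config[[st]] %||% list(), state, outdir,
                     stage_seed(seed, st)),
      error = function(e)
        stop_micello("stage_failure", "stage '%s' failed: %s", st,
                     conditionMessage(e)))
    res$seed <- stage_seed(seed, st)
    res$checksums <- as.list(tools::md5sum(unlist(res$files %||% list())))
    manifest$stages[[st]] <- res
  }
  write_config(manifest, file.path(outdir, "manifest.yaml"))
  manifest$outdir <- outdir
  invisible(manifest)
}

pipeline_stage <- function(stage, par, state, outdir, seed) {
  f <- function(...) file.path(outdir, paste0(...))
  switch(stage,
    simulate = {
      shape <- par$shape %||% "prolate"
      nb <- par$n_beads %||% 5000L
      if (shape %in% c("sphere", "prolate")) {
        dims <- as.numeric(par$dims %||% c(37.5, 21, 21))
        e <- make_ellipsoid(dims[1], dims[2], dims[3], nb, seed)
        state$model <- e$model; state$truth <- e$truth
      } else if (shape == "coreshell") {
        dims <- as.numeric(par$dims %||% c(15, 30))
        state$model <- make_core_shell_sphere(dims[1], dims[2],
                                              par$w_core %||% 1,
                                              par$w_shell %||% 1, nb, seed)
        state$truth <- NULL
      } else if (shape == "aggregate") {
        agg <- make_aggregate(par$n_monomers %||% 20L, seed = seed)
        state$coords <- agg
        state$model <- bead_model(positions_of(agg), label = "aggregate")
        state$truth <- NULL
      } else stop_micello("config_error", "unknown shape '%s'", shape)
      prof <- if (isTRUE(par$smeared)) pipeline_profile(par$profile %||% list())
      state$profile <- prof
      state$curve <- make_noisy_curve(state$model,
                                      q_grid = par$q_grid %||% seq(0.02, 0.6, by = 0.004),
                                      noise_frac = par$noise %||% 0.01,
                                      smear_profile = prof, seed = seed + 1L)
      files <- list(beads = f("beads.pdb"), curve = f("curve.dat"))
      write_coordinates(state$model, files$beads)
      write_curve(state$curve, files$curve)
      if (!is.null(state$truth)) {
        files$truth <- f("truth.yaml")
        write_config(list(shape = state$truth$shape,
                          semi_axes = state$truth$semi_axes,
                          dmax = state$truth$dmax, rg = state$truth$rg,
                          axial_ratio = state$truth$axial_ratio), files$truth)
      }
      list(parameters = par, files = files)
    },
    desmear = {
      if (is.null(state$curve)) stop_micello("config_error", "no curve in state")
      sw <- par$smooth_window %||% 11L
      if (sw > 0L) state$curve <- smooth_curve(state$curve, sw)
      state$curve <- desmear(state$curve, state$profile %||%
                               pipeline_profile(par$profile %||% list()),
                             max_iter = par$max_iter %||% 30L,
                             tol = par$tol %||% 1e-4)
      files <- list(curve = f("curve_desmeared.dat"))
      write_curve(state$curve, files$curve)
      list(parameters = par, files = files)
    },
    ift = {
      if (is.null(state$curve)) stop_micello("config_error", "no curve in state")
      lambda <- par$lambda %||% "auto"
      if (!is.null(par$scan)) {
        sc <- scan_dmax(state$curve,
                        seq(par$scan$from, par$scan$to, by = par$scan$by),
                        n_basis = par$n_basis %||% 20L, lambda = lambda,
                        q_min_cut = par$q_min_cut %||% 0.04)
        dmax <- attr(sc, "recommended")
        state$dmax_scan <- sc
      } else dmax <- par$dmax %||% 90
      state$ift <- ift_fit(state$curve, dmax, n_basis = par$n_basis %||% 20L,
                           lambda = lambda, q_min_cut = par$q_min_cut %||% 0.04)
      files <- list(pr = f("pr.dat"), fit = f("curve_fit.dat"),
                    diag = f("ift_diagnostics.yaml"))
      write_pr(state$ift$pr, files$pr)
      write_curve(scattering_curve(state$ift$data$q, state$ift$fitted),
                  files$fit)
      write_config(list(dmax_support = dmax, n_basis = state$ift$basis$n,
                        lambda = state$ift$lambda, chi2 = state$ift$chi2,
                        chi2_reduced = state$ift$chi2_reduced,
                        n_excluded = state$ift$n_excluded), files$diag)
      list(parameters = par, files = files)
    },
    shape = {
      if (is.null(state$ift)) stop_micello("config_error", "no ift fit in state")
      rep <- shape_report(state$ift$pr, floor_frac = par$floor_frac %||% 0.01)
      state$shape <- rep
      files <- list(report = f("shape.yaml"))
      write_config(list(dmax = rep$dmax,
                        dmax_scan = if (!is.null(state$dmax_scan))
                          attr(state$dmax_scan, "recommended"),
                        rg = rep$rg,
                        cross_section = rep$cross_section,
                        axial_ratio = rep$axial_ratio,
                        asymmetry = rep$asymmetry), files$report)
      list(parameters = par, files = files)
    },
    compare = {
      if (is.null(state$model) || is.null(state$ift))
        stop_micello("config_error", "compare needs a model and an ift fit")
      geo <- principal_extents(state$model)
      sh <- state$shape %||% shape_report(state$ift$pr)
      sc <- scale_to(predict(state$ift, q = state$ift$data$q,
                             smeared = state$ift$data$smeared),
                     state$ift$data)
      cmp <- list(model = list(rg = geo$rg, height = geo$height,
                               width = geo$width, axial_ratio = geo$axial_ratio),
                  pr = list(rg = sh$rg, dmax = sh$dmax,
                            cross_section = sh$cross_section,
                            axial_ratio = sh$axial_ratio),
                  curve_match = list(scale = sc$scale, chi = sc$chi))
      state$comparison <- cmp
      files <- list(comparison = f("comparison.yaml"))
      write_config(cmp, files$comparison)
      list(parameters = par, files = files)
    },
    titrate = {
      tc <- make_titration(par$pKa %||% 7.2,
                           lambda_acid = par$lambda_acid %||% 340,
                           lambda_base = par$lambda_base %||% 440,
                           pH_grid = par$pH_grid %||% seq(2.4, 11.1, by = 0.5),
                           noise_nm = par$noise_nm %||% 0.2, seed = seed)
      fitp <- hh_fit(tc)
      state$titration <- fitp
      files <- list(table = f("titration.dat"), fit = f("titration_fit.yaml"))
      write_titration(tc, files$table)
      write_config(list(pKa = fitp$pKa, pKa_se = fitp$pKa_se,
                        plateau_acid = fitp$plateau_acid,
                        plateau_base = fitp$plateau_base, rms = fitp$rms),
                   files$fit)
      list(parameters = par, files = files)
    })
}
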