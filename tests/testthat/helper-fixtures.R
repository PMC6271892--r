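# Shared fixtures, computed lazily and cached for the whole test run.
# The heavy objects (Debye sums over thousands of beads) are built once.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# 20,000-bead sphere of radius 20 A plus its Debye curve on a sparse grid
# (q R <= 6); the workhorse for the sphere-oracle checks.
sphere_beads <- function() fixture("sphere_beads", function() {
  make_ellipsoid(20, 20, 20, n_beads = 20000L, seed = 42)
})

sphere_debye <- function() fixture("sphere_debye", function() {
  debye_intensity(sphere_beads()$model, seq(0.02, 0.30, by = 0.02))
})

# The full reduction chain on the prolate micelle model (75 x 42 x 42 A,
# slit-smeared, 1% noise, smoothed, desmeared, IFT): the flagship
# end-to-end fixture shared by the acceptance tests.
prolate_chain <- function() fixture("prolate_chain", function() {
  e <- make_ellipsoid(37.5, 21, 21, n_beads = 5000L, seed = 1)
  prof <- slit_profile("trapezoid", t1 = 0.05, t_max = 0.2)
  curve <- make_noisy_curve(e$model, noise_frac = 0.01,
                            smear_profile = prof, seed = 1001)
  des <- suppressWarnings(desmear(smooth_curve(curve, 11L), prof,
                                  max_iter = 15L))
  fit <- ift_fit(des, dmax = 90, n_basis = 20L, lambda = "auto",
                 q_min_cut = 0.04)
  list(truth = e$truth, model = e$model, profile = prof, curve = curve,
       desmeared = des, fit = fit, shape = shape_report(fit$pr))
})

# Small prolate (cheap Debye) for smearing round trips.
small_prolate <- function() fixture("small_prolate", function() {
  e <- make_ellipsoid(30, 18, 18, n_beads = 1500L, seed = 7)
  list(truth = e$truth, model = e$model,
       curve = debye_intensity(e$model, seq(0.02, 0.6, by = 0.004)))
})

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol * abs(expected)),
              label = sprintf("max rel diff %.3g vs tol %.3g",
                              max(abs(actual - expected) / abs(expected)), tol))
}
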