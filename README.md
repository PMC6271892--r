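# micellometry

Characterization of surfactant micelles (and other nanoscale particles)
from small-angle X-ray scattering and from molecular coordinate models,
in one tested R package.

Micelle-forming glycosides such as the *Quillaja saponaria* saponins are
studied with two independent rulers: SAXS curves measured on the solution,
and coordinate models (bead models or MD snapshots) of the aggregate.
micellometry implements the full analysis both rulers need:

* **Reduction** of slit-collimated (Kratky camera) data: cubic
  moving-polynomial smoothing, iterative (Lake-type) desmearing of the
  beam-length convolution, absolute-scale calibration against the water
  standard (1.68 × 10⁻²).
* **Indirect Fourier transformation (IFT)**: the pair-distance
  distribution p(r) expanded in N cubic B-splines on [0, D_max] with
  p(0) = p(D_max) = 0, coefficients from stabilized least squares
  minimizing Σ[(I_k − (Ac)_k)/σ_k]² + λΣ(c_{i+1} − 2c_i + c_{i−1})²,
  automatic λ, support scanning, and the option to fit slit-smeared data
  directly through a smeared design matrix.
* **Shape descriptors from p(r)**: maximum dimension D_max, radius of
  gyration via Rg² = ∫r²p dr / 2∫p dr, the transverse cross-section from
  the inflection of p(r) between its maximum and the linear decay, and
  the equivalent axial ratio D_max / cross-section.
* **Forward scattering** from bead models by the exact Debye sum
  I(q) = ΣΣ wᵢwⱼ sin(qr_{ij})/(qr_{ij}) (compiled, O(n²)), exact pair
  histograms, the 4π∫p(r)sinc(qr)dr back transform, and least-squares
  scale/χ matching of model curves to experiment.
* **Coordinate-space descriptors**: mass-weighted radius of gyration,
  principal-axis height/width/axial ratio, radial distribution functions
  g(r), Shrake–Rupley solvent-accessible surface area, IUPAC-signed
  dihedral angles, and logarithmic growth-trend fits (dim = a + b ln n).
* **Titration**: Henderson–Hasselbalch sigmoid fits,
  λ(pH) = λ_A + (λ_B − λ_A)/(1 + 10^(pKa − pH)), with standard errors.
* **Synthetic data with ground truth**: seeded bead ellipsoids,
  core–shell spheres, amphiphile-shell aggregates, solvated boxes, noisy
  (optionally slit-smeared) curves and titration tables, so every stage
  is testable offline.
* **IO**: whitespace q/I(/σ) curve files, p(r) tables, PDB and GRO
  coordinates (GRO converted from nm to Å), titration tables, YAML run
  configs.

## Worked example

Invert a scattering curve of a 20 Å sphere and read its shape back:

```r
library(micellometry)
q     <- seq(0.02, 0.6, by = 0.004)
curve <- sphere_form_factor(20, q, i0 = 1000)   # analytic test particle
fit   <- ift_fit(curve, dmax = 50, n_basis = 20, lambda = "auto",
                 q_min_cut = 0.04)
summary(fit)
#> Indirect Fourier transform fit
#>   141 points (5 excluded below q = 0.04), 20 splines on [0, 50] A
#>   lambda = 3.276e-07, chi2 = 4.698e-09 (reduced 3.82e-11)
#>   I(0) = 1000
#> Shape descriptors from p(r):
#>   D_max            39.31 A
#>   Rg               15.49 A
#>   cross-section    32.87 A
#>   axial ratio       1.20
#>   asymmetry       -0.219
```

The recovered D_max (39.3 Å) and Rg (15.49 Å) match the sphere's true
diameter 40 Å and closed-form Rg = √(3/5)·20 = 15.49 Å; the "cross
section" and axial ratio 1.20 illustrate the documented floor of the
inflection rule — even a perfect sphere reads as apparent ratio ≈ 1.2,
so only values clearly above that indicate elongation.

Fit a titration curve:

```r
tc <- make_titration(7.2, pH_grid = seq(2.4, 11.1, 0.5), noise_nm = 0.2,
                     seed = 42)
hh_fit(tc)
#> Henderson-Hasselbalch fit
#>   pKa = 7.19 +/- 0.00
#>   plateaus: 340.1 nm (acid) -> 439.9 nm (base)
#>   residual RMS 0.200 nm over 18 points
```

The full simulate → desmear → IFT → shape → compare chain runs from one
config:

```r
run_pipeline(system.file("extdata", "demo_run.yaml",
                         package = "micellometry"),
             outdir = "demo_out")
```

which writes the bead model, curves, p(r), a shape report and a
model-vs-scattering comparison table, plus a manifest with parameters and
checksums (bit-identical on rerun).

See the vignette (`vignettes/micelle-characterization.Rmd`) for the
models, the numerical choices and the known limitations.

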