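# headspectra

Spatial-frequency analysis of EEG-like scalp potentials on arbitrary sensor
surfaces.

The head is a spatial low-pass filter: the skull and the depth of cortical
sources smear scalp potentials, so only a limited band of spatial
frequencies ever reaches an electrode array. `headspectra` quantifies that
band and what discrete sensor layouts do to it. It is aimed at people who
design EEG electrode arrays, spatial filters or source-analysis pipelines
and need concrete numbers for *how much spatial detail exists on the scalp*
and *how densely it must be sampled*.

## What is inside

**Semi-analytical four-shell forward model.** Concentric spheres
(brain/CSF/skull/scalp; radii 80/81/86/92 mm, conductivities
0.33/1.79/0.0066/0.33 S/m by default). The scalp potential of a dipole at
eccentricity *f* = r/R₄ is a Legendre series whose degree-l term is weighted
by (2l+1)⁴ f^(l−1)/C(l); the shell factor C(l) comes from the multilayer
boundary-value problem, evaluated in ratio-scaled form that is stable to
l = 600 and reduces exactly to (2l+1)³ for equal conductivities. Because
the degree-l term carries only degree-l Legendre structure, per-degree
surface energies are available in closed form — no mesh, no quadrature.

**Sphara (spatial harmonic analysis).** The generalized spatial Fourier
basis on an arbitrary triangulated sensor layout: linear-FEM cotangent
stiffness S and consistent mass B, eigenproblem S x = τ B x, B-orthonormal
modes, wavelength λ = 2π/√τ. Works on open electrode caps, where a genuine
spatial-DC component appears.

**Discrete real spherical harmonics.** Geodesy 4π-normalized basis (no
Condon–Shortley phase), least-squares fitted at scattered points — the
classical benchmark on the sphere, used to validate Sphara.

**Analyses.** Equidistant layout generation (seeded distmesh-style
repulsion) with edge statistics and spatial Nyquist limits (λ_N = 2·h_max);
depth-dependent energy gain; per-degree energy spectra; energy
misestimation of discrete layouts over a 7700-source ensemble; SH-vs-Sphara
agreement; percentile and depth-group spectral envelopes for lead-field
bundles.

## Worked example

Generate two classic layouts on a 92 mm head sphere, inspect their spatial
Nyquist limits, and ask how much energy superficial sources carry:

```r
library(headspectra)

layouts <- sensor_layouts(c(34, 104), radius = 92, seed = 1)
layouts[, c("n", "n_triangles", "h_mean", "h_max", "lambda_n")]
#> # A tibble: 2 × 5
#>       n n_triangles h_mean h_max lambda_n
#>   <dbl>       <int>  <dbl> <dbl>    <dbl>
#> 1    34          64   59.7  71.6    143.
#> 2   104         204   34.5  40.8     81.6
```

The 34-sensor (10–20-equivalent) layout has a Nyquist wavelength of about
143 mm: scalp patterns finer than that alias. The 104-sensor layout resolves
down to ~82 mm.

```r
energy_gain_curve(radii = c(0, 50, 76))
#> # A tibble: 5 × 5
#>   radius_mm orientation energy ratio    db
#>       <dbl> <chr>        <dbl> <dbl> <dbl>
#> 1         0 free          141.  1    0
#> 2        50 radial        182.  1.28 1.09
#> 3        50 tangential    171.  1.21 0.819
#> 4        76 radial        285.  2.01 3.04
#> 5        76 tangential    241.  1.70 2.31
```

A superficial radial source emits twice the scalp energy of a central one
(+3 dB), a tangential one 1.7×. Where does the extra energy live? In higher
spatial frequencies:

```r
term_spectrum(radii = c(0, 70), orientations = "radial", l_max = 5)
#> # A tibble: 10 × 6
#>    radius_mm orientation     l lambda_mm fraction      db
#>  1         0 free            1      409.   1         0
#>  2         0 free            2      236.   0      -Inf
#>  ...
#>  6        70 radial          1      409.   1         0
#>  7        70 radial          2      236.   0.443    -3.53
#>  8        70 radial          3      167.   0.176    -7.56
#>  9        70 radial          4      129.   0.0710  -11.5
#> 10        70 radial          5      106.   0.0301  -15.2
```

The central source lives entirely at degree 1 (wavelength 409 mm); a source
19 mm below the scalp adds components at 236 mm, 167 mm and beyond — which
is exactly the content a coarse array fails to capture. The full pipelines
(`run_validate_sphere()`, `run_analyze_leadfield()`) chain these steps and
write delimited tables, a resolved config and a JSON summary.

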