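---
title: "Spatial spectra of scalp potentials: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial spectra of scalp potentials: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headspectra)
```

## The problem

The head acts as a spatial low-pass filter: cortical current sources produce
scalp potential patterns whose fine spatial structure is attenuated by the
poorly conducting skull and by source depth. How much spatial detail survives
— and how densely the scalp must be sampled to capture it — matters for EEG
sensor-array design, spatial filtering, source reconstruction and power
analyses. `headspectra` quantifies this with three interlocking tools:

1. a **semi-analytical four-shell spherical forward model** whose Legendre
   series gives exact, discretisation-free per-degree energy contributions;
2. **spatial harmonic analysis (Sphara)**: a generalized spatial Fourier
   basis from the Laplace–Beltrami eigenproblem on an arbitrary triangulated
   sensor layout, applicable to open, irregular surfaces;
3. **discrete real spherical harmonics** fitted by least squares, the
   classical benchmark on the sphere.

Everything runs on synthetic data generated by the package itself.

## Four-shell forward model

The volume conductor is four concentric spheres — brain, CSF, skull, scalp —
with radii $R_1 < R_2 < R_3 < R_4$ (defaults 80/81/86/92 mm) and isotropic
conductivities $\sigma_1,\dots,\sigma_4$ (defaults 0.33/1.79/0.0066/0.33
S/m). For a unit current dipole at eccentricity $f = r/R_4$ on the $z$-axis,
the scalp potential is a Legendre series whose degree-$l$ term carries
$P_l(\cos\theta)$ (for the $z$ moment) or $P_l^1(\cos\theta)\cos\phi$,
$P_l^1(\cos\theta)\sin\phi$ (for $x$, $y$ moments, divided by $l$), weighted
by $(2l+1)^4 f^{\,l-1} / C(l)$ and the prefactor $1/(4\pi\sigma_4 R_4^2)$.
Arbitrary dipole positions are handled by rotation to this canonical frame
(`rotate_to_canonical()`).

The shell factor $C(l)$ is computed from the standard multilayer
boundary-value problem — continuity of potential and radial current density
at the three internal interfaces, zero radial current at the scalp — written
as a product of $2\times2$ interface and propagation matrices. Two
properties make this formulation the one we trust:

* every radius power enters as a ratio $(R_i/R_j)^{2l+1} \le 1$, so the
  evaluation neither overflows nor loses precision up to $l = 600$;
* with equal conductivities it reduces *exactly* to $(2l+1)^3$, recovering
  the classical insulated homogeneous sphere. The test suite verifies this
  reduction, checks $C(l)$ against an independently coded dense solve of the
  same boundary-value problem, and pins a handful of values computed in
  exact rational arithmetic.

Radii are converted to metres internally so that potentials are volts for a
1 A·m moment; every relative or dB quantity is invariant to this choice.

Because the degree-$l$ term is the only one carrying $P_l$, squaring and
integrating over the scalp sphere gives **closed-form per-degree energies**
(`term_energy()`), using $\oint P_l^2\,d\Omega = 4\pi/(2l+1)$ and
$\oint (P_l^1)^2 \cos^2\!\phi \, d\Omega = 2\pi\,l(l+1)/(2l+1)$. Energies of
distinct degrees are additive; the series for a total energy
(`total_surface_energy()`) is truncated when a term falls below `tol`
(default $10^{-10}$) of the running sum, with a hard cap at $l = 600$ —
generous, since $f \le 76/92$ makes the tail decay geometrically.

Two facts anchor the analyses: a central source excites *only* $l = 1$ (its
energy is the 0 dB reference of the spherical analyses), and the $l = 1$
energy of a unit source is identical at every depth and orientation, so all
energy gained by superficial sources arrives in higher spatial frequencies.

## Sphara: the Laplace–Beltrami eigenbasis

On a triangulated layout, piecewise-linear FEM discretises the
Laplace–Beltrami operator into a cotangent stiffness matrix $S$ and a mass
matrix $B$; the generalized eigenproblem $S x = \tau B x$ yields
$B$-orthonormal basis vectors with eigenvalues $\tau$ (mm$^{-2}$) that map
to wavenumber $k = \sqrt{\tau}$ and wavelength $\lambda = 2\pi/k$. The
discrete energy of a sampled field is the quadratic form $f^\top B f$, and
the analysis transform $c_i = f^\top B x_i$ is unitary: $\sum c_i^2 =
f^\top B f$ when all modes are kept.

Design choices:

* **Consistent (not lumped) mass matrix** — per triangle of area $A$:
  $A/6$ diagonal, $A/12$ off-diagonal. This preserves the $B$-inner-product
  structure that makes the transform unitary. A lumped variant would change
  per-mode energies at the sub-percent level; we fix the consistent form and
  document it rather than exposing a switch, because the energy bookkeeping
  in the tests assumes a single convention.
* **Dense generalized solver via Cholesky of $B$** for every mesh size used
  here (up to 4000 vertices, ~30 s). A sparse shift-invert route would be
  preferable for much larger meshes, but no suitable sparse generalized
  eigensolver is among the package's dependencies, and the dense route is
  exact, deterministic and comfortably within budget — so it is the
  implementation, not a fallback.
* **Sign convention**: each eigenvector is flipped so its largest-magnitude
  entry is positive, making spectra reproducible across LAPACK builds.
* **Degenerate-eigenvalue tie-break**: eigenvalues are returned ascending;
  within a numerically degenerate group the dense solver's ordering is kept.
  All degree-grouped quantities are invariant to this.
* Open meshes (electrode caps) need no special treatment: natural boundary
  conditions are implicit in the FEM assembly, and the constant mode keeps
  $\tau \approx 0$.

On a sphere the spectrum is degenerate in blocks of $2l+1$; after skipping
the DC mode, consecutive blocks are mapped to spherical-harmonic degrees
(`mode_degrees()`). This is exact on the sphere and declared approximate
elsewhere. Discrete eigenvalues overshoot $l(l+1)/R^2$ slightly (the mesh
chords are shorter than arcs), so Sphara wavelengths sit a few percent
*below* the Jeans wavelengths — the expected negative bias, which shrinks
under mesh refinement.

## Spherical harmonics

Real spherical harmonics use the geodesy $4\pi$ normalization with no
Condon–Shortley phase: $\bar P_l^m = \sqrt{(2-\delta_{0m})(2l+1)
\frac{(l-m)!}{(l+m)!}}\,P_l^m$, cosine branch for $m \ge 0$, sine branch for
$m < 0$. Coefficients on scattered points come from ordinary least squares
through a rank-revealing QR factorisation, with no regularisation — failure
is preferred to silent smoothing, and rank deficiency is reported.

Sampling bounds: Gauss–Legendre grids need $(l+1)(2l+1)$ points and
Driscoll–Healy grids $(2l+2)^2$. For $n$ scattered, approximately
equidistant points we bound the resolvable degree by
$l_{up} = \lfloor\sqrt{n/2} - 1\rfloor$, the inversion of the
Gauss–Legendre count $N \approx 2l^2$ (the printed form of this bound in the
source material is typographically damaged; this is the only reading
consistent with the quadrature counts, and it gives $l_{up} = 43$ at
$n = 4000$). Requests beyond $l_{up}$ are refused with guidance rather than
fitted anyway.

## Sensor layouts and the spatial Nyquist limit

Equidistant layouts are generated by seeded repulsion in the distmesh
manner: Fibonacci-lattice initialisation with a small seeded jitter, then
truncated repulsive springs along the edges of the current spherical
Delaunay triangulation (recomputed from the convex hull as points move,
target length 1.2 times the RMS edge length, explicit steps of 0.2), with
reprojection to the sphere and termination when the largest per-sweep
displacement drops below $10^{-4}$ radius. The construction is
deterministic in `(n, radius, seed)`. Its edge statistics reproduce the
published distmesh layouts closely — e.g. for 34 points on a 92 mm sphere,
mean/max edge lengths 59.7/71.6 mm against the published 59.73/71.52 mm,
and for 4000 points 5.57/6.69 mm — which is what qualifies the generator to
stand in for the original tool. An earlier all-pairs inverse-square variant
matched mean edge lengths but produced 5–11% longer maximum edges; the
local-spring scheme was adopted for that reason.

For an irregular mesh the conservative sampling bound is set by the longest
edge: $\lambda_N = 2 h_{max}$, $\omega_N = 1/(2h_{max})$,
$k_N = \pi/h_{max}$ — a worst-case limit ensuring no aliasing even in the
sparsest region.

## The synthetic source ensemble

The study conditions are 100 approximately equidistributed unit sources on
each of 77 concentric shells (radii 0–76 mm, 1 mm steps, 7700 positions),
simulated with radial moments and with tangential moments of seeded random
azimuth; the 100 central sources get seeded random orientations, since no
radial/tangential distinction exists there. Per-shell positions reuse the
same seeded repulsion as the layouts (the original random streams are
unspecified; only distributional properties are reproduced). These defaults
are the generator's — analyses may subset them, but the geometry itself is
not a tuning knob.

## The analyses

* **Energy gain vs depth** (`energy_gain_curve()`): closed-form total
  energies relative to the central source. Superficial radial sources carry
  slightly more than double the central energy; tangential ones about 1.7×.
* **Sampling misestimation** (`sampled_energy_deviation()`): for every
  ensemble source, the discrete energy $f^\top B f$ of the potential
  sampled at a layout, versus the exact series energy; reported as the
  signed relative deviation, with "misestimates by up to X%" meaning the
  maximum of its absolute value. Coarse layouts underestimate
  systematically: partly the area deficit of the inscribed polyhedron,
  partly spatial frequencies above the layout's Nyquist limit.
* **Spectra** (`sh_spectrum()`, `sphara_spectrum()`): per-degree energy
  fractions of forward fields at a dense (4000-point) layout, referenced to
  the mean energy of the 100 central sources. dB is the energy convention
  $10\log_{10}$, so 50% ≈ −3 dB.
* **Within-depth spread**: reported for *degree-grouped* (2l+1-summed)
  Sphara contributions, which are rotation-invariant in the continuum and
  vary across same-depth sources only through the discreteness of the mesh.
  Per-mode contributions are *not* comparable across same-depth sources —
  rotating a source redistributes energy freely inside a degenerate block
  (for central sources, the three $l=1$ modes trade the full 100% among
  themselves) — so a per-mode spread would be dominated by that geometric
  freedom rather than by numerical fidelity.
* **Open-surface route** (`run_analyze_leadfield()`): any lead field on a
  (possibly open) sensor mesh — imported from text files or synthesised by
  the four-shell model on a spherical cap — is decomposed in the Sphara
  basis of that mesh. The 0 dB reference is the median energy of the 15
  deepest sources. Percentile envelopes (median, 90th, 99th, 99.9th, max)
  and six depth-group maximum envelopes summarise the spectrum; the depth
  groups default to equal-count sextiles because no published group edges
  exist — an explicit `edges` argument overrides this. On open surfaces a
  genuine DC component appears, because the surface no longer encloses the
  sources; it is physics, not artefact.

## Problem sizes and what the tests show

The test suite exercises the full 4000-point spectral comparison with 900
ensemble sources (five shells × 100 positions × both orientation classes),
and the sampling-misestimation analysis at 20 sources per shell over all 77
shells; the acceptance script (`scripts/acceptance.R`) runs the
misestimation analysis at the full 100 per shell. These sizes are the
package's chosen working points: large enough that every reported statistic
is stable to well within its tolerance, small enough to run interactively.

Passing tests demonstrate internal consistency on the *spherical* model
only: agreement of three independent routes (closed-form series, discrete
spherical harmonics, Sphara) and faithful reproduction of the documented
sampling biases. They do not certify behaviour on realistic anatomy — real
heads break the degeneracy structure, have position-dependent sensor
coverage, and anisotropic tissue in reality violates the isotropic
conductivity assumption entirely. Measurement noise is also absent: all
fields are noiseless forward solutions.

## Numerical conventions, in one place

| quantity | choice | default |
|---|---|---|
| series truncation | per-term energy < `tol` × running total | `1e-10`, cap $l=600$ |
| eigen tolerance | dense LAPACK; τ clamped to 0 if within `1e-8·max` below 0 | — |
| eigenvector sign | largest-magnitude entry positive | — |
| B-orthonormality | exact via Cholesky transform | checked ≤ `1e-8` |
| LSQ | QR, no regularisation, rank reported | — |
| dB | $10\log_{10}$ (energy) | 0 → −∞ sentinel |
| units | mm for geometry, S/m for σ, volts internally via m | — |
| degenerate inputs | zero-area triangles, non-manifold edges, off-sphere points, $|m|>l$, negative τ: all rejected with specific errors | — |

## Known limitations

* The spherical degree-grouping of Sphara modes is heuristic on non-spherical
  meshes; per-degree comparisons there should be read qualitatively.
* Sphara wavelengths carry the documented negative bias at coarse sampling
  (>10% below ~100 vertices); quantitative wavelength work needs dense
  layouts.
* Very small spectral contributions (below about −90 dB) are at the floor of
  double-precision least squares and are not determined reliably.
* The lead-field import route trusts the caller's geometry: lead fields are
  validated for shape, not re-derived physics.
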