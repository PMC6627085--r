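---
title: "Methods: thin-film indentation elastography and voltage-dye analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thin-film indentation elastography and voltage-dye analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntk)
```

This vignette documents the models implemented by `ntk`, the assumptions
behind them, the defaults and why they were chosen, what the synthetic
generators do and do not emulate, and the numerical decisions made where the
underlying protocol leaves the design open. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. Indentation model

A rigid sphere (radius $R$, density $\rho_s$) rests on a hydrogel film of
thickness $h$, immersed in aqueous supernatant (density $\rho_m$). The load
is the buoyant weight

$$F = \tfrac{4}{3}\pi R^3 (\rho_s - \rho_m)\, g,$$

and classical Hertz contact for an elastic half-space gives

$$E_\mathrm{Hertz} = \frac{3\,(1-\nu^2)\,F}{4\,R^{1/2}\,\delta^{3/2}}.$$

For films whose thickness is comparable to the contact scale the half-space
assumption fails. With the confinement parameter
$\omega = \sqrt{R\delta}/h$ and frictionless sphere/gel and gel/substrate
contact, the thin-film-corrected modulus is

$$E_\mathrm{modified} = E_\mathrm{Hertz}\,
  \frac{1 + 2.3\,\omega}{1 + 1.15\,\omega^{1/3} + \alpha\omega +
  \beta\omega^2},
  \qquad \beta = 4.8 - 4.23\,(h/R)^2,$$

valid for $0.3 \le R/h \le 12.7$ and $\delta/h \le \min(0.6,\,R/h)$
(inclusive bounds; ratio comparisons carry a $10^{-9}$ relative slack so a
boundary ratio constructed in floating point, such as $R = 0.3h$, passes).

### Design choices the source leaves open

* **Poisson ratio.** Never stated for these gels; the default is
  $\nu = 0.5$ (incompressible, water-dominated material, consistent with
  the frictionless framing). Configurable in `elasticity_config()`.
* **Load.** The applied force is never written out; the buoyant sphere
  weight is used because the indenters rest immersed in the supernatant.
  Medium density and $g$ are configurable in `medium_spec()`.
* **Hertz exponent.** The flattened source text reads $\delta^{2/3}$; the
  classical, dimensionally consistent $\delta^{3/2}$ is implemented
  ($F \propto \delta^{3/2}$ in Hertz contact).
* **Grouping of $\alpha$.** After typographic flattening the coefficient
  expression is ambiguous. Two readings are shipped:
  `printed` (default, literal token order)
  $\alpha = 10.05 - 0.63\,(h/R)\,(3.1 + h^2/R^2)$, and `fraction`
  $\alpha = (10.05 - 0.63\,h/R)/(3.1 + h^2/R^2)$. Both coincide in the
  thick-sample limit $\omega \to 0$.
* **Denominator guard.** For $h/R \gtrsim 1.07$, $\beta < 0$ (and under the
  `printed` grouping $\alpha$ also turns negative), so the correction
  denominator is a polynomial that changes sign *inside* the stated
  validity domain. A denominator at or below the configurable floor
  ($10^{-9}$) raises a typed error (`ntk_nonpositive_denominator_error`)
  rather than returning a negative or infinite modulus.

### Consequences of the sign change: reachable moduli

Near $R/h = 0.3$ the denominator pole limits the usable depth range and
creates a minimum reachable $E_\mathrm{modified}$ for a given load: with
the 1/32" Si$_3$N$_4$ ball on a 1.3 mm gel the forward model cannot
produce moduli in the 100–500 Pa softness band relevant for neural
scaffolds under either grouping. The inverse solver
(`invert_indentation()`) therefore pre-scans the forward model
(`indentation_domain()`), restricts itself to the maximal strictly
decreasing, positive-denominator depth range, and raises
`ntk_no_root_error` for unreachable targets. The synthetic scene generator
defaults to $h = 400\ \mu m$ (so $R/h \approx 1$ for the default
indenter), where both groupings are well-behaved and the 100–500 Pa band
is reachable; this is the stated world of the end-to-end recovery tests.

### A deliberate red test

The acceptance suite asserts, verbatim, that
$E_\mathrm{modified}/E_\mathrm{Hertz}$ is within $10^{-3}$ of 1 at
$\omega = 10^{-6}$. That is unattainable for this closed form: the
deviation is governed by the $1.15\,\omega^{1/3}$ term and equals
$\approx 1.1\times10^{-2}$ at $\omega = 10^{-6}$; $10^{-3}$ closeness
first holds near $\omega \approx 6\times10^{-10}$. The unit suite asserts
the true monotone $\omega^{1/3}$ convergence (within $10^{-3}$ at
$\omega = 10^{-12}$, exact at $\omega = 0$); the acceptance test is left
failing rather than weakened.

## 2. Stack profiling

Stacks are $(z, y, x)$ arrays, slice 0 nearest the objective, slice-centre
positions in micrometres. A `z_origin` field supports stacks that image
only the surface region.

* **Thickness** comes from the green (gel) channel's mean axial profile:
  moving-average smoothing (default window 3 slices; 5 recommended at 5%
  noise), first difference, gel bottom at the maximum positive derivative
  and top at the most negative. Each boundary is the derivative-weighted
  centroid of the contiguous half-max run around the extremum — exact on
  noiseless slabs (the smoothing spreads an edge symmetrically) and about
  half a window more precise than a bare argmax under noise, which is what
  makes the $\pm 2\ \mu m$ noisy-slab behaviour achievable. A profile whose
  maximum absolute derivative is zero or below $3\times$ the median
  absolute derivative raises `ntk_flat_profile_error`.
* **Refractive index.** Acquisition at refractive index 1.33 may or may not
  already be folded into exported z-steps by the instrument. Default:
  trust the metadata (scale 1); setting `z_corrected = FALSE` multiplies
  nominal steps by the index. This avoids double correction.
* **Depth** comes from the red (bead) channel: per column, the surface is
  the intensity-weighted axial centroid of the brightest contiguous blob
  (half-max run around the argmax); columns below 10% of the channel
  maximum are masked. The undisturbed level is the median elevation over
  the outer 20% annulus; the floor is the minimum of the 3×3-smoothed map
  over the interior; $\delta$ is their difference. A depression whose
  global minimum touches the field border *and* is deeper than two z-steps
  raises `ntk_edge_depression_error` (off-centre indenter); the depth
  qualifier prevents flat noisy fields from tripping it. The full-map
  minimum replaces the visual two-cross-section reading of the original
  protocol; `cross_section()` provides the XZ/YZ views for parity.

## 3. Voltage-dye analytics

With dye-only background wells pooled into $F_0$, each well's 25 reads give
$\Delta F/F_0$ values and

$$\Delta E = \frac{RT}{z' F}\,\ln\!\frac{1}{\Delta F/F_0 + 1}
  \qquad (\mathrm{mV};\ RT/F = 25.43\ \mathrm{mV\ at\ 295.15\ K}).$$

The argument grouping $\ln(1/(\Delta F/F_0 + 1))$ is the unique reading
consistent with the calibration plot ($1/(\Delta F/F_0+1)$ against
$K_x/K_r$) and gives positive $\Delta E$ (depolarization) for fluorescence
increases when $z' < 0$. Defaults: $T = 295.15$ K to match the printed
thermal voltage; $z' = -0.64$, inside the $-0.62$ to $-0.72$ range reported
for neuronal cultures.

* **Calibration fit space.** "Slope of the best fit line" does not name the
  axes transform. Default is log-log ordinary least squares of
  $\ln(1/(\Delta F/F_0+1))$ on $\ln(K_x/K_r)$ — exactly the linearization
  of the model, so noiseless data return the generating $z'$ to solver
  precision; a direct `linear` regression is offered as a variant.
* **COV.** Computed on raw reads (100·SD/mean, sample SD). The normalized
  $\Delta F/F_0$ can cross zero and break the ratio; raw-read COV is
  scale-invariant and equals the COV of $F$. Wells are flagged at the 5%
  and 10% thresholds; exclusion only happens when the analysis plan says
  so.
* **Tests.** "One-way" testing is implemented as one-sided $p$-values:
  pooled-variance two-sample $t$ ($df = n_1+n_2-2$) for between-culture
  comparisons and paired $t$ ($df = n-1$) for stimulated-vs-rest, with the
  direction declared in the plan (default: first group greater). Zero
  within-pair variance with a nonzero shift is degenerate and reported as
  an infinite $t$ with a typed warning.

## 4. Synthetic generators: what they emulate

* **Scenes** render the green slab as a boxcar plateau and the bead layer
  as a Gaussian axial profile (width 1.5 µm) centred on the surface, with
  the indenter imprint as a spherical cap of the indenter radius; the
  depth is obtained from the target modulus through the forward model's
  own inverse, so scene truth is model-consistent by construction.
  Defaults: 64×64 columns, field of four contact radii (≥ 200 µm), 5 µm
  coarse stack for thickness and 1 µm fine stack for depth (mirroring the
  two acquisition settings), 5% multiplicative Gaussian intensity noise.
  Not emulated: optical PSF blur beyond the Gaussian layer, bead
  granularity, far-field surface dimpling, gel autofluorescence gradients,
  or refractive mismatch artefacts — a green end-to-end test therefore
  establishes estimator correctness on idealized geometry, not robustness
  to those instrument effects.
* **Plates** generate reads as $F = F_0(\Delta F/F_0 + 1)(1+\varepsilon)$,
  $\varepsilon \sim N(0, \mathrm{cv})$, from per-group true $\Delta E$
  means via the exact inverse of the conversion; 25 reads per well,
  dye-only wells included, default read noise 2% (COV well under the 10%
  QC bound, matching reported plate behaviour). The density–$\Delta E$
  link is a configurable linear map; linearity is emulated, not asserted
  mechanistically.
* **Titrations** draw $1/(\Delta F/F_0+1) = (K_x/K_r)^{z'}(1+\varepsilon)$
  per cell at $K_x = 5.4, 10, 15, 20, 25$ mM, 50 cells/point, 5% noise —
  the stated world of the $z'$-recovery acceptance target.
* All generators are bit-reproducible given (parameters, seed), and restore
  the caller's RNG state.

## 5. Numerical choices and degenerate inputs

* Inverse solver: depth bracket $[10^{-12}\ \mathrm{m},\,
  h\min(0.6, R/h)]$ on a 200-point log grid, root polishing with
  `uniroot` in log-depth, residual checked to $10^{-9}$ relative.
* Validity comparisons: inclusive with $10^{-9}$ relative slack (Section 1).
* Zero indentation: $\omega = 0$ returns $E_\mathrm{Hertz}$ exactly;
  $\delta = 0$ makes the Hertz modulus undefined and raises a domain
  error.
* Replicates: sample SD ($n-1$); a single replicate reports NA dispersion
  with a typed warning. SEM is emitted alongside SD because the source's
  "±" convention is not defined.
* Serialization is plain text (CSV + JSON side-car metadata) at 15
  significant digits; stacks round-trip to ~$10^{-12}$ relative.

## 6. Known limitations

* Frictionless thin-film correction only: no adhesion (JKR/DMT), bonded
  boundaries, or viscoelasticity.
* One indenter per field; the depth estimator assumes an interior,
  roughly centred depression.
* Static plate reads only; no kinetic action-potential detection.
* $\Delta E$ is a change relative to the dye-equilibrated baseline, not an
  absolute resting potential.
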