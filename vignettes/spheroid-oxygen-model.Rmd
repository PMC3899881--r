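---
title: "Methods: the spheroid oxygen model, its estimators, and the synthetic validation world"
author: "spheroidO2 authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the spheroid oxygen model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroidO2)
```

## The model

Avascular multicellular tumour spheroids are supplied with oxygen only by
diffusion from the surrounding medium. At steady state, with a constant
volumetric consumption rate $a$ (m$^3$ of O$_2$ gas per kg of tissue per
second), the oxygen content obeys the spherical Poisson equation
$\nabla^2 C = a/D$, where $D$ is the tissue diffusion coefficient. Converting
oxygen content per tissue mass into partial pressure through Henry's law
introduces a single lumped constant $\Omega$ (mmHg kg m$^{-3}$), so that in
the oxygenated shell $r_n < r \le r_o$

$$p(r) = \frac{a\,\Omega}{6D}\left(r^2 + \frac{2 r_n^3}{r} - 3 r_n^2\right),$$

with $p = 0$ and zero flux at the anoxic-core boundary $r_n$, and
$p(r_o) = p_o$ at the surface. Three derived quantities organise everything
the package does:

* the **diffusion limit** $r_l = \sqrt{6 D p_o / (a \Omega)}$, the largest
  radius a spheroid can reach while still oxygenated at its centre. It
  depends on the physiology ($a$, $D$, $p_o$) but not on the spheroid's
  actual size, which is what makes it usable as a consumption-rate probe;
* the **anoxic core radius** $r_n$, the root of the characteristic cubic
  $2 r_n^3 - 3 r_o r_n^2 + (r_o^3 - r_l^2 r_o) = 0$ inside $(0, r_o)$ when
  $r_o > r_l$, and $0$ otherwise;
* the **rim limit** $r_m = r_l/\sqrt{3}$, the infimum of the viable rim
  thickness $r_c = r_o - r_n$ as the spheroid grows.

The estimation direction inverts these relations: measured boundaries give
$r_l = \sqrt{r_o^2 + 2 r_n^3/r_o - 3 r_n^2}$ per spheroid, and
$a = 6 D p_o / (\Omega r_l^2)$. The radius of any isobar $p$ is the root of
$r^3 - (3 r_n^2 + r_l^2\, p/p_o)\, r + 2 r_n^3 = 0$ on $[r_n, r_o]$; the
10 mmHg isobar is of particular interest because 2-nitroimidazole hypoxia
markers (such as EF5) bind maximally below roughly that pressure, so the
interface between proliferation-marker and hypoxia-marker staining in a
dual-stained section is an experimentally visible isobar.

## Parameters, units, and defaults

All internal lengths are metres and all pressures mmHg; conversions to
micrometres happen only at the I/O boundary. The defaults in
`oxygen_params()` describe tumour tissue treated as water-like:

| parameter | default | meaning |
|---|---|---|
| `D` | $2\times10^{-9}$ m$^2$ s$^{-1}$ | O$_2$ diffusion coefficient (water-like tissue) |
| `p_o` | 100 mmHg | partial pressure at the spheroid surface |
| `Omega` | $3.0318\times10^{7}$ mmHg kg m$^{-3}$ | lumped Henry's-law conversion |
| `K` | $2.2779\times10^{-4}$ m$^3$ mmHg kg$^{-1}$ | Henry's constant (informational) |
| `rho_O2` | 1.331 kg m$^{-3}$ | O$_2$ gas density |
| `rho_T` | 1000 kg m$^{-3}$ | tissue density |
| `M_O2` | 0.032 kg mol$^{-1}$ | O$_2$ molar mass |

`Omega` is adopted as a printed numeric constant rather than re-derived from
`K` and the gas density: its symbolic definition involves a unit-bookkeeping
subtlety (numerically $\Omega \approx \rho_{O_2} K \times 10^{11}$), but the
constant is self-consistent — it reproduces the benchmark consumption-rate
triple ($r_l$ = 233/211/255 µm $\leftrightarrow$ $a$ = 7.29/8.89/6.09
$\times10^{-7}$ m$^3$ kg$^{-1}$ s$^{-1}$) exactly, which the acceptance tests
pin down.

## Numerical choices

* **Cubic roots.** Both cubics are solved by safeguarded bracketing
  (`uniroot`) in normalised variables ($x = r_n/r_o$), not by the closed
  trigonometric form. Sign analysis guarantees the bracket: the
  characteristic cubic is positive at $0$ and negative at $r_o$ whenever
  $r_o > r_l$, so the interior root exists, is unique, and is found to
  $\sim10^{-14}$ relative tolerance (well below the 1 pm absolute target).
  The tests anchor correctness to independent bisection oracles on the same
  polynomials.
* **Sub-limit regime.** For $r_o \le r_l$ there is no core; the symmetric
  solution $p(r) = p_o - (a\Omega/6D)(r_o^2 - r^2)$ is used, and the
  per-spheroid estimator reports $r_l = r_o$ flagged `sub_limit` (a lower
  bound, not an estimate).
* **Anoxia threshold.** The model sets $p(r_n) = 0$ exactly. Cells are
  already severely hypoxic slightly above zero ($\sim$0.8 mmHg), but moving
  the boundary condition there changes nothing material; zero is the
  model's own boundary condition and is kept.
* **Michaelis–Menten variant.** `solve_mm_profile()` replaces constant
  uptake with $a_{max}\, p/(p + k_m)$ and solves the boundary-value problem
  on a uniform grid (default 4000 intervals) with a damped Newton iteration
  and tridiagonal (Thomas) linear solves; the symmetric stencil
  $6(p_1 - p_0)/h^2$ imposes zero flux at the centre. Exactly $k_m = 0$ is
  an obstacle problem (the uptake switches off discontinuously where
  $p = 0$), so $k_m$ is floored at $10^{-4}$ mmHg; the perturbation this
  causes is orders of magnitude below the 0.5 mmHg acceptance gate, as the
  tests verify. Convergence is declared at a $10^{-8}$ mmHg residual, with
  a grid-halving consistency check in the tests; non-convergence raises an
  error carrying the residual.

## The image-analysis algorithm

`measure_section()` reproduces a transparent 360-ray protocol:

1. **Segmentation and centroid.** The union (pixel-wise max) of the stain
   channels is thresholded (Otsu by default — the original protocol's
   "certain threshold" is unspecified, and the steep stain gradients make
   the result insensitive to it, a property the tests check at ±20%
   threshold). Connected components smaller than 1% of the largest are
   dropped: this automates the manual removal of dislodged stain debris.
   Interior holes (the unstained anoxic core) are filled, and the
   intensity-weighted centroid located.
2. **Outer boundary** $r_o$: per 1° ray, the largest occupied-mask radius,
   marching inward from the image edge (bilinear interpolation, 0.25 px
   radial step).
3. **Anoxic boundary** $r_n$: per ray, the smallest radius with
   supra-threshold stain, marching outward from the centroid. A stained
   centroid means no core ($r_n = 0$).
4. **Stain interface**: per ray, the outermost radius at which the
   (per-channel normalised) hypoxia stain still dominates the proliferation
   stain, interpolated at the dominance crossing, considering only radii
   where stain is present. Detections beyond $r_o$ or inside $r_n$ — the
   signature of detached stain artefacts — are excluded with a recorded
   reason; a cohort-level orientation check rejects swapped channel
   assignments. The original description mentions only an "average point of
   transition"; the outermost-dominance rule is this package's concrete
   reading, chosen because it reproduces the documented artefact behaviour,
   and it is validated only on synthetic data.
5. **Summaries**: means and population standard deviations over the
   non-excluded rays (360 values per quantity), converted to µm via the
   mandatory user-supplied scale (sections carry no physical pixel size).

Pixel conventions: integer pixel centres, origin top-left, y down, angles
counter-clockwise from +x.

## The synthetic world

`render_section()` draws the three concentric regions the model implies —
unstained core to $r_n$, hypoxia-stain annulus to the interface isobar
(default 10 mmHg), proliferation-stain annulus to $r_o$ — and perturbs them
with the realism knobs that matter for this measurement problem:

* smooth angular jitter: a random-phase sum of order 2–6 sinusoids,
  normalised to a stated RMS amplitude and applied multiplicatively to all
  boundaries (sectioning deforms the whole section coherently). Default
  20 µm, matching the 16–30 µm per-image boundary standard deviations
  reported for real dual-stained sections;
* an elliptical warp (default axis ratio 0.95);
* Gaussian optical blur (default 2 px) over piecewise-constant stain
  levels, keeping gradients steep but not pixel-sharp;
* background Gaussian noise (default s.d. 0.05 of full scale);
* detached stain blobs outside the spheroid (default 2), exercising the
  artefact-exclusion path.

These defaults were chosen once as the stated validation world and are not
tuned. What the generator deliberately does **not** emulate: photorealistic
microscopy (PSF shape, uneven illumination, chromatic registration errors),
cell-scale texture, stain intensity heterogeneity within a region, and
spheroid-to-spheroid biological variability of the diffusion limit. A green
recovery test therefore establishes that the measurement chain is unbiased
and precise against geometry of known truth under realistic deformation and
noise — not that it reproduces every failure mode of real sections.

`generate_cohort()` renders n spheroids with radii evenly covering a stated
range under one ground-truth $r_l$ ("evenly" rather than uniformly at
random, for deterministic coverage of the size range);
`apply_consumption_drift()` re-renders with the consumption rate dropping
linearly across the size-ordered cohort, the scenario the sensitivity
analysis is meant to detect.

## Sensitivity analyses and their anchoring

`sensitivity_consumption_drift()` refits the interface predictions under
$a_i = a_{agg}\,(1 - f\,(i-1)/(n-1))$ for each stated total drop $f$,
size-ordered, anchored at the cohort-aggregate rate for the smallest
spheroid so that $f = 0$ reproduces `compare_interface()` exactly. On data
generated under constant consumption the fit degrades monotonically with
$f$. Whether it reaches negative $R^2$ at $f = 0.75$ depends on the cohort
geometry: for the synthetic world used here (radii evenly spanning
250–500 µm) the drift deviations amount to about 78% of the
measured-interface variance, bounding $R^2$ near $+0.2$; datasets whose
interface measurements span a narrower range can and do go negative. The
package reports the full table rather than hard-coding an expectation.

`sensitivity_interface_pressure()` evaluates the interface isobar at the
ends of a pressure band (default 8–12 mmHg, a ±20% error on the
hypoxia-marker binding threshold) and reports the largest per-spheroid
absolute difference — single-digit micrometres for realistic geometries.
The comparator is reported as a full per-spheroid table because the
corresponding published figure does not state which spheroid or which
pairwise comparison it refers to.

## Aggregation conventions

Per-spheroid diffusion limits are pooled as mean ± sample standard
deviation; the cohort consumption rate is the estimator evaluated **at the
mean** $r_l$, with asymmetric bounds from re-evaluating at mean ± 1 s.d.
(this is how the benchmark three-row table is constructed, and it is exact
arithmetic — no data needed). A single-spheroid cohort reports its s.d. as
absent, not zero. $R^2 = 1 - SS_{res}/SS_{tot}$ is computed against the
measurement mean and may be negative; zero-variance measurements make it
undefined (reported `NA` with a warning).

## Known limitations

* The model is time-independent: it predicts the oxygen structure of a
  spheroid of given size, not growth trajectories. Glucose co-limitation,
  vascularised geometries, and 1-D multicellular-layer variants are out of
  scope.
* The viable rim converges to $r_m$ slowly ($O(1/r_o)$): 2% above the limit
  at $r_o = 10\,r_l$, 0.2% at $100\,r_l$. Distinguishing $r_c$ from $r_m$
  experimentally requires precision better than typical sectioning
  deformation.
* Below the diffusion limit the boundary-derived $r_l$ is only a lower
  bound ($r_o$ itself); such spheroids are flagged, not silently pooled.
* Image I/O covers PNG, plain-text NetPBM and CSV matrices; TIFF is not
  supported (no TIFF reader is available in the supported dependency set).
* The per-image measurement bias grows with physical blur per pixel: at
  2.5 µm/px and 2 px blur the diffusion-limit bias is about −3%, within
  the 5% recovery gate; coarser scales trade accuracy for speed.
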