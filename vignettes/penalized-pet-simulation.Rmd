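---
title: "Simulating penalization-factor sweeps in PET reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating penalization-factor sweeps in PET reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(PETsimIQ)
```

## What the package models

Modern PET scanners offer regularized (Bayesian penalized-likelihood)
reconstruction alongside classical OSEM. The regularizer's single user knob —
the penalization factor β — trades noise suppression against contrast and
resolution, and the clinically interesting question is where on the β grid
(here 0.03–0.5) image quality is best for a given tracer and acquisition
time. PETsimIQ reproduces that experiment end to end in simulation:

1. **Synthetic truth volumes.** A digital NEMA image-quality phantom (four
   hot spheres of 10/13/17/22 mm diameter filled at 13.2 kBq/mL over a
   background at one quarter of that concentration) and a patient-like
   volume (elliptical torso at SUV 1, uniform ellipsoidal liver at SUV 5.96,
   spherical lesions spanning the <10 / 10–20 / ≥20 mm diameter strata).
2. **Forward model.** Per-slice 2D parallel-beam projection with an
   isotropic Gaussian resolution blur (default FWHM 4 mm) applied in the
   image domain before projection, and independent Poisson counts drawn at
   count budgets that stand in for 2 vs 3 minutes-per-bed acquisitions.
3. **Reconstruction.** Standard OSEM (2 iterations × 20 subsets, 3 mm
   Gaussian post-filter) and a one-step-late (OSL) total-variation penalized
   EM swept over the β grid at both duration classes — the 16 arms
   O2, O3, HR2.03 … HR3.5.
4. **Evaluation.** NEMA-style phantom metrics (contrast recovery CR,
   background variability BV, CNR = CR/BV, radioactivity concentration
   ratio RCR, normalized activity), clinical metrics (liver coefficient of
   variation in a 3-cm spherical VOI, 41%-of-SUVmax lesion segmentation,
   equivalent diameter, normalized SUVmax), and paired statistics
   (D'Agostino–Pearson gate, paired t or exact Wilcoxon signed-rank,
   Benjamini–Hochberg correction per metric family).

## The penalized reconstruction stand-in

The vendor algorithm being emulated is proprietary; its published
description names three ingredients — a pixel-to-pixel total-variation
penalty, a global noise-equivalent-counts weighting, and a local sensitivity
profile — with β as the only user parameter. The package's declared stand-in
composes exactly those ingredients around the EM update. For subset $S$ with
sensitivity $s_j^S$, the OSL update divides by

$$ s_j^S + \frac{\beta_{\mathrm{eff},j}}{\#\text{subsets}}
   \cdot \frac{\partial R}{\partial x_j}\Big|_{x^{(k)}}, \qquad
   \beta_{\mathrm{eff},j} = \beta\,\kappa
   \sqrt{\frac{N_{\mathrm{ref}}}{N_{\mathrm{total}}}}\; w_j , $$

where $R$ is the ε-smoothed isotropic total variation
($\varepsilon = 10^{-3}\times$ the mean nonzero initialization value, fixed
per run), $w_j$ the sensitivity image normalized to unit mean inside the
field of view, $N_{\mathrm{total}}$ the counts actually acquired and
$N_{\mathrm{ref}}$ a reference count level (default: the calibrated 3 m/b
patient budget, so the factor is 1 at the reference condition and larger for
shorter or poorer acquisitions). The modified denominator is floored at
$0.1\,s_j^S$ so positivity survives large negative penalty gradients. With
β = 0 the update is bit-for-bit standard OSEM (one shared code path).

### Iteration schedule

The penalized arms run the same 2 iterations × 20 subsets as the OSEM arms.
This is a deliberate design choice, made after measuring the alternative:
run near convergence (10 × 20), the unregularized limit of the OSL stand-in
reaches ≈ 41 % liver CV (3 m/b) — noise no clinical algorithm would emit —
and the low-β arms inherit most of it (34–41 %), while the emulated
algorithm sits near 14 % across its whole β grid. Because the OSL penalty
acts multiplicatively per update, its relative effect across the β grid is
nearly independent of the iteration count; only the unregularized ceiling
moves. Matching the clinical OSEM schedule bounds that ceiling at the noise
level the clinical protocol itself accepts (≈ 16 % at 3 m/b unfiltered) and
yields a CV profile of ≈ 15 → 7 % (3 m/b) and ≈ 17 → 9 % (2 m/b) across
β = 0.03–0.5 — structurally close to the reference behavior. A
relative-change stopping tolerance (1e-4, L2) is retained but is not reached
on this schedule.

### One-time calibrations (then frozen)

* **Patient count budget.** The 3 m/b budget is fixed by matching the OSEM
  3 m/b liver CV to the 12.88 % reference level
  (`calibratePatientBudget()`, a damped fixed point using the
  CV ∝ counts^(-1/2) scaling, averaging 3 noise realizations per step
  because a single 3-cm-VOI CV has ≈ 8 % realization spread). Result:
  ≈ 4.8e6 counts per bed at 3 m/b, 2 m/b exactly 2/3 of that
  (`patientBudget(base2 = 3.2e6)`). The phantom budgets default to 2.0e6
  counts for the 31-s-equivalent frame and scale by 46/31 for the
  46-s-equivalent one; only the ratio is physically meaningful.
* **Penalty scale κ.** κ is a single global constant fixed once so that the
  β = 0.2, 3 m/b arm is noise-equivalent to OSEM 3 m/b (normalized CV in
  (0.9, 1.05)). κ = 0.8 gives normalized CV ≈ 0.95 stably across seeds and
  is frozen as the `PemProtocol()` default.

## What the generator does and does not emulate

The generator reproduces the statistical structure the analysis needs:
compartment contrasts (4:1 phantom spheres; liver/background/lesion SUVs),
SUV calibration (suvScale = injected activity [kBq] per gram body weight;
default 97.2 MBq / 61.3 kg ≈ 1.59 MBq/kg), lesion size strata, Poisson
counting noise at duration-scaled budgets, and finite resolution. Boundary
voxels carry sub-voxel volume-weighted mixtures (3×3×3 center subsampling)
to avoid staircase bias in CR at 10–22 mm sphere sizes; a binary
center-in/out mode exists for exact-ratio tests.

It deliberately omits: attenuation/scatter/randoms (the simulated data are
treated as perfectly pre-corrected), time-of-flight, anatomy beyond the
liver and lesions, respiratory motion, tracer kinetics — and, importantly,
**biological tissue texture**. The synthetic liver is uniform, so its VOI CV
is pure reconstruction noise. In patients, a sizeable share of the measured
liver CV is anatomical heterogeneity that regularization preserves; that is
the parsimonious reading of the reference profile being nearly flat in β
(≈ 13.5 → 11 % over a 17× β range) while a pure-noise CV falls much more
steeply. Consequences for the package's benchmarks: with the budget pinned
to the OSEM reference CV and κ pinned by the noise-equivalence window, the
lowest-penalty 2 m/b arm lands at ≈ 17–19 % CV — above the 15 % clinical
ceiling that all arms satisfy in vivo. The corresponding acceptance check is
expected to flag exactly this arm; it measures the uniform-liver idealization,
not a defect of the reconstruction code. Passing phantom tests likewise show
correctness of the metrics and the direction and ordering of β effects, not
quantitative agreement with any particular scanner.

## Numerical choices

* **Projector.** Ray-driven Joseph-style bilinear interpolation sampled at
  the in-plane voxel size, materialized once per (grid, geometry) as a
  sparse matrix; the adjoint is its literal transpose, so the
  projector/backprojector pair is exact to machine precision (verified
  against a column-by-column materialization on small grids). Default
  geometry: 60 angles over 180°, radial bins at the 3.12 mm voxel pitch
  covering the grid diagonal.
* **Gaussian blur.** Explicit sparse 1D convolution matrices with
  cell-integrated (erf) kernels and reflected edges; totals are conserved
  and the adjoint is again the transpose, which makes the EM
  count-conservation identity hold to 1e-6.
* **Subsets.** Angles are assigned to subsets by stride (angle index mod
  subsets) and processed in natural order; the subset count must divide the
  angle count.
* **Initialization.** Uniform image equal to total counts / Σ sensitivity
  inside the field of view; zero outside. Zero-count data reconstruct to an
  exactly zero image.
* **Degenerate inputs.** ROI/VOI means require at least one voxel center
  inside; CV requires a positive mean; lesion segmentation refuses seeds in
  flat background (SUVmax ≤ 1.2 × local median); RCR/CR/BV/CNR validate
  their denominators.
* **SD conventions.** Population (n) SD for both the background-ROI spread
  and the liver VOI, for determinism; the sample convention is a switch.
* **Normalization conventions.** Reference group O3 maps to exactly 1;
  lesion SUVmax and liver CV are normalized per lesion/replicate first and
  averaged afterwards (mean-of-ratios), which is why the reference group
  reports SD 0.
* **Seeds.** One master seed; per-(duration, replicate) substreams are
  derived arithmetically (all below 2³¹), so replicates can be re-ordered
  without changing their draws, and all arms of one duration class
  reconstruct the same counts — as rebinning a single list-mode acquisition
  would.

## Problem sizes

Full-scale runs (the acceptance script and the acceptance tests) use the
reference conditions: 192 × 192 in-plane at 3.12 × 3.12 × 2.68 mm³, a
single-slice phantom stack, and a 20-slice patient slab. The unit and
property tests exercise the same code paths at reduced sizes chosen for
quick iteration — 64² single-slice phantoms, 96 × 96 × 10 patient slabs at
4 × 4 × 5 mm³, 40 projection angles — with 5 seeded replicates for the
monotonicity properties. Reduced scale changes noise levels, not the
orderings and invariances the tests assert.

## Statistics

Small replicate counts are routed to the nonparametric branch outright
(n < 20, a declared validity floor for the omnibus normality test); larger
samples use the D'Agostino–Pearson K² gate at α = 0.05. The Wilcoxon
signed-rank test drops zero differences, average-ranks ties, enumerates all
sign assignments exactly for n ≤ 12 (ties included), and uses the
tie-corrected normal approximation with continuity correction above.
Benjamini–Hochberg adjustment is applied per metric family across the 15
non-reference arms; the family definition is a declared choice.

## Known limitations

* The penalized algorithm is a declared stand-in, not the vendor's method;
  absolute metric values are not comparable to any scanner, only
  within-simulation contrasts are meaningful.
* Single-slice phantom physics (no inter-slice scatter of signal); the
  patient slab couples slices only through the 3D TV penalty.
* No lesion-detection task: lesion seeds are inputs.
* The uniform liver makes the CV-vs-β profile steeper than in vivo (see
  above); likewise lesion SUVmax gains of the penalized arms over OSEM stem
  only from the absent post-filter and TV edge preservation, and are smaller
  than clinically reported gains.
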