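# PETsimIQ

Simulation bench for studying how the penalization factor of a regularized
(total-variation penalized) expectation-maximization PET reconstruction
trades noise against contrast, compared with standard OSEM.

Regularized ("Bayesian penalized-likelihood") reconstruction replaces the
OSEM recipe of early stopping plus Gaussian post-filtering with a roughness
penalty whose single user knob, the penalization factor β, controls the
noise/resolution trade-off. Choosing β for a given tracer and acquisition
time is an empirical question usually answered with a NEMA image-quality
phantom and a patient cohort. PETsimIQ reproduces that whole experiment in
silico, for people who want to study the β response of a penalized
reconstruction under controlled conditions: it generates a digital NEMA
phantom (four hot spheres, 10/13/17/22 mm, filled 4:1 over background) and
synthetic patient volumes (uniform liver at SUV ≈ 6, low-uptake body,
spherical lesions across size strata), simulates Poisson projection data at
2- and 3-minute-per-bed-equivalent count budgets, reconstructs 16 arms —
OSEM at both durations (O2, O3) and a one-step-late TV-penalized EM over
β ∈ {0.03, 0.07, 0.1, 0.2, 0.3, 0.4, 0.5} at both durations (HR2.03 …
HR3.5) — and computes the full quantitative surface.

The core quantities, per hot sphere j:

    CR_j  = (C_H,j / C_B,j − 1) / (a_H / a_B − 1) × 100%   (contrast recovery)
    BV_j  = SD_j / C_B,j × 100%                            (background variability)
    CNR_j = CR_j / BV_j
    RCR_j = measured sphere / background concentration      (≤ true ratio 4)

and, on patient images: liver CV = SUV_sd/SUV_mean in a 3-cm spherical VOI,
41%-of-SUVmax threshold lesion segmentation with equivalent diameter
D = (6V/π)^(1/3), per-lesion SUVmax normalization against the O3 reference,
stratified by D (<10, 10–20, ≥20 mm), injected activity (1.60 MBq/kg) and
BMI (24 kg/m²), with normality-gated paired tests (paired t / exact Wilcoxon
signed-rank) and Benjamini–Hochberg correction.

The penalized algorithm is a declared stand-in for proprietary vendor
regularization: an ε-smoothed total-variation penalty incorporated
one-step-late into the EM denominator, scaled by β, a frozen global
constant, a √(reference/actual counts) factor, and the normalized local
sensitivity — see the methods vignette (`vignettes/`) for the model, its
calibrations, and its limitations.

## Worked example

Reconstruct the default phantom at the 3 m/b-equivalent budget with OSEM
and with the penalized algorithm at β = 0.2, and evaluate the NEMA metrics:

```r
library(PETsimIQ)

spec  <- NemaPhantomSpec()              # 10/13/17/22 mm spheres, 13.2 kBq/mL, 4:1
grid  <- VoxelGrid()                    # 192 x 192, 3.12 mm pixels, single slice
geom  <- ProjectionGeometry(grid = grid)
truth <- buildNemaPhantom(spec, grid)

counts <- simulateData(truth, geom, phantomBudget(3, seed = 1))
o3 <- osemReconstruct(counts, OsemProtocol(), grid, geom,
                      label = makeGroupLabel("OSEM", 3))
hr <- pemReconstruct(counts, PemProtocol(beta = 0.2), grid, geom,
                     label = makeGroupLabel("PEM", 3, 0.2))

layout <- layoutRois(spec, grid)
round(measureSphereMetrics(o3, layout, spec), 2)
#>   sphere diameter    cH   cB   sd    cr   bv   cnr  rcr
#> 1      1       10  9.21 3.32 0.18 59.11 5.56 10.62 2.77
#> 2      2       13 10.28 3.29 0.16 70.76 4.72 14.98 3.12
#> 3      3       17 10.71 3.30 0.12 74.71 3.52 21.20 3.24
#> 4      4       22 11.43 3.30 0.07 81.97 2.25 36.35 3.46
round(measureSphereMetrics(hr, layout, spec), 2)
#>   sphere diameter    cH   cB   sd    cr   bv   cnr  rcr
#> 1      1       10  9.45 3.32 0.15 61.66 4.60 13.40 2.85
#> 2      2       13 10.54 3.29 0.14 73.29 4.21 17.42 3.20
#> 3      3       17 10.90 3.30 0.11 76.65 3.20 23.93 3.30
#> 4      4       22 11.57 3.30 0.07 83.33 2.15 38.68 3.50
```

Reading the output: the background mean `cB` recovers the true 3.3 kBq/mL;
contrast recovery falls short of 100% and RCR stays below the true ratio 4
because finite resolution smears small spheres (partial-volume effect),
most severely for the 10 mm sphere. At β = 0.2 the penalized arm suppresses
background variability (`bv`) below OSEM's while holding slightly higher
contrast, so CNR improves for every sphere — the core phenomenon the
penalization-factor sweep quantifies.

The 16-arm experiment with replicates, group aggregation, normalization
against O3 and paired statistics is one call:

```r
res <- runSweep(sweepConfig(mode = "phantom", masterSeed = 7, replicates = 5),
                outDir = "results/phantom")
head(res$groupMetrics)
```

Patient-mode sweeps (`mode = "patient"`) report liver CV, normalized CV,
lesion SUVmax and normalized SUVmax per arm, with the same comparisons.

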