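---
title: "Methods: graph-based retinal layer segmentation and normative thickness analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-based retinal layer segmentation and normative thickness analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`retlayer` measures retinal layer thinning in mouse SD-OCT volumes. This
vignette documents the model behind each stage, the tunable parameters and
why their defaults are what they are, what the synthetic phantom does and
does not emulate, and the numerical choices and limitations a user should
know before trusting the output.

## 1. The segmentation model

A B-scan is a depth × A-scan intensity image in which retinal layer
boundaries appear as horizontal intensity transitions. All four boundaries
this package detects — vitreous/ILM, INL/OPL, ONL/ISe and OS/RPE — are
*dark-to-bright* transitions when traversed downward, so detection reduces
to finding horizontal ridges of positive vertical gradient.

Each pixel becomes a graph node; directed edges connect a pixel to its
up-right, right and down-right neighbours, which enforces exactly one row
per column and a lateral slope limit of one pixel per column. The edge
weight between nodes $a$ and $b$ is

$$ w_{ab} = 2 - (g_a + g_b) + w_{\min}, $$

with $g$ the positive vertical gradient normalised to $[0,1]$ and
$w_{\min} = 10^{-5}$ a floor that keeps all weights positive. A
minimum-total-weight left-to-right path, computed by Dijkstra's algorithm,
therefore follows the strongest dark-to-bright ridge. One zero-weight
virtual column on each side lets the path enter and exit at any row, so no
endpoint constraint is imposed; a path across $n$ columns accumulates
$n-1$ weighted edges.

Two properties are worth noting:

* **Normalisation invariance.** Every admissible path has exactly $n-1$
  edges, so any affine rescaling of $g$ shifts all path costs equally and
  cannot change which path is minimal. The gradient is normalised once
  over the whole image, not per search region.
* **Deterministic tie-breaking.** The priority queue orders nodes by
  (cost, column, *deeper row first*) and relaxation is strict, so repeated
  runs give identical paths. Preferring the deeper row matters: after
  symmetric smoothing, the two rows straddling a rasterised boundary carry
  identical gradient, and the boundary row proper is the first row of the
  brighter, deeper layer. With the shallow-row preference the detected
  line sits systematically ~1 px high; with the deeper-row convention the
  noise-free recovery error is the rounding residual (≤ 0.5 px).

### Detection order and search regions

The four interfaces are found in a fixed order, each stage restricting the
next stage's admissible region: (1) vitreous/ILM on the full image — the
largest gradient in the image, hence the globally lowest-weight path;
(2) OS/RPE below the ILM path; (3) INL/OPL between ILM and OS/RPE;
(4) ONL/ISe between INL/OPL and OS/RPE. A guard band (`guard`, default
2 px) is excluded against each bounding path so a stage cannot re-detect
an already-found ridge. This order is only well posed if the gradient
magnitudes rank ILM > OS/RPE > INL/OPL > ONL/ISe, which holds for murine
SD-OCT reflectance and is enforced in the phantom (section 4).

### Operator correction

`refine_interface()` emulates the manual re-cut used in practice: the
search region is narrowed to `band_halfwidth` pixels around a hand-drawn
polyline (linearly interpolated over its column span; a band around the
current path elsewhere) and the minimum-weight path is re-solved. The
result is re-validated against neighbouring interfaces; a correction that
would cross them raises an ordering error. Re-segmentation does not
cascade to downstream interfaces — the caller decides whether to re-run
later stages.

## 2. Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `sigma` | `c(0.3, 1.5)` | px (vertical, lateral) | Vertical SD 0.3 gives a 3-tap kernel whose radius stays inside the thinnest bright bands (ISe, RPE ≈ 3 px at 3.9 µm pitch); larger vertical SDs let the negative transition below those bands pull the gradient ridge half a pixel upward. Speckle suppression comes from the lateral kernel instead, which cannot bias the vertical position of locally horizontal boundaries. |
| `w_min` | 1e-5 | – | Keeps weights positive so Dijkstra is valid; small enough not to distort ridge preference. |
| `guard` | 2 | px | Just wider than the half-width of a smoothed gradient ridge, preventing duplicate detection while leaving thin anatomical gaps (ONL/ISe to OS/RPE ≈ 6.7 px) feasible. |
| `band_halfwidth` | 5 | px | Operator corrections need local freedom to snap to the true ridge but must not escape to a neighbouring one. |
| `axial_pitch` | 3.9 | µm/px | Instrument axial sampling; converts rows to microns. Lateral pitch never enters thickness. |
| disk exclusion | 1.5 × diameter | grid units | Rectangular window (|Δhoriz| and |Δvert| both < 1.5 D); an elliptical window with the same semi-axes is available (`shape = "ellipse"`). The rectangle matches the "horizontally and vertically" reading; the difference only affects the window's corners. |

Thickness definitions (shared boundaries): IRT = ILM→INL/OPL,
ORT = INL/OPL→OS/RPE, TRT = IRT + ORT, OSL = ONL/ISe→OS/RPE. TRT is
computed *as the sum*, so the conservation identity TRT = IRT + ORT holds
at machine precision rather than to floating-point rounding.

## 3. Normative model and Z-scores

The normative model stores the per-pixel sample mean and SD (denominator
$n-1$) of each measure across wild-type eyes, on the jointly valid pixel
set. Z-scores are computed only where the model SD is positive; degenerate
pixels are excluded rather than assigned infinite scores. Area fractions
bin Z into $(-\infty,-1)$, $[-1,1]$ and $(1,\infty)$ — boundary values
fall in the closed middle bin — and always sum to 100 % before rounding.
The cohort summary averages per-eye fractions and reports
`reduced_minus_increased`, the difference between mean reduced and mean
increased area percentages.

By default the pipeline builds one normative model per age group, because
wild-type thickness drifts slightly with age; a pooled model over all
wild-type eyes is available (`normative_mode = "pooled"`). No conclusion
drawn by the package's tests depends on this choice.

**Calibration caveat.** When between-eye variability dominates (as the
study-calibrated phantom cohorts are built to reproduce), all pixels of an
eye share that eye's thickness deviate. Pooled bin fractions then carry
*eye-level* sampling error — roughly $\sqrt{p(1-p)/K}$ for $K$ eyes, i.e.
several percentage points — rather than per-pixel binomial error, and two
independent small cohorts can differ by a substantial fraction of an SD by
luck alone. The package's calibration test therefore uses leave-one-out
Z-scoring within a single wild-type cohort, which removes the cohort-mean
term exactly by symmetry, and checks the Gaussian bin values themselves on
independent standard-normal scores. Real normative databases face the
same issue; per-age models with a dozen eyes estimate the population mean
to only ±0.3 SD.

## 4. The synthetic phantom

`generate_phantom()` builds a Spectralis-like raster (31 B-scans, 1536
A-scans, 3.9 µm axial pitch; lateral sampling reducible for speed) from a
layered geometric model:

* **Anatomy.** Nine layers (NFL+GCL, IPL, INL, OPL, ONL, IS, ISe, OS,
  RPE) with wild-type thicknesses calibrated so the global measures are
  IRT/ORT/TRT/OSL = 94/114/208/26 µm at 12 weeks and 96/115/211/26 µm at
  24 weeks. The ELM, a sub-pixel band at this sampling, is not modelled.
* **Reflectance.** Bright NFL+GCL/IPL/OPL/ISe/RPE over dark
  INL/ONL/IS/OS, with values chosen so the smoothed gradient magnitudes
  rank ILM (0.29) > OS/RPE (0.23) > INL/OPL (0.18) > ONL/ISe (0.12) >
  ONL/IS (0.03) — the ordering the fixed detection sequence requires, with
  enough margin to survive speckle and per-eye thickness perturbations.
* **Shape.** A smooth sinusoidal surface undulation (10 µm lateral, 6 µm
  across B-scans), identical in every eye, so it cancels in normative
  statistics; slopes stay far below the 1 px/column connectivity limit.
* **Optic disk.** A Gaussian-profile thickening of the inner layers near
  the disk centre (default 40 % at centre, σ = 0.75 diameter), placed near
  the nasal edge. Only the exclusion logic is tested against it; its slope
  exceeds the path slope limit at the core, which is precisely the region
  the disk exclusion removes.
* **Vessel shadows.** Columnwise attenuation (×0.55) below the
  superficial vasculature at nine fixed positions, so IRT/TRT maps show
  vessel traces and the segmentation must cope with locally weakened
  outer-retinal gradients.
* **Speckle.** Multiplicative gamma noise with unit mean and coefficient
  of variation `speckle_level` (default 0.30, shape ≈ 11) — a standard
  first-order model for multi-frame-averaged OCT speckle. The noise-free
  intensity profile steps exactly at the rasterised ground-truth
  interfaces (rounded half-up; sub-pixel truth retained for error
  scoring).

`generate_cohort()` adds per-eye normal perturbations of the three layer
groups (between-eye SDs 4.4/2.5/2.0 µm for inner/outer/outer-segment,
matched to the spread of published wild-type cohorts), diabetic thinning
fractions per age group that reproduce the reference percent differences
in expectation (12 wk: −2.13 % inner, −2.27 % outer, 0 % OSL; 24 wk:
−4.17 %, −3.38 %, 0 %), laterality (left eyes mirrored at acquisition,
~32 % of eyes), body weight, and blood glucose: wild-type N(151, 19²) and
N(139, 19²) mg/dL by age; diabetic values a hyperglycemic floor (269/380)
plus a gamma tail, censored at the 600 mg/dL glucometer ceiling with the
censored flag recorded (~40 % of diabetic readings hit the ceiling). OSL
thinning is fixed at zero — the reference cohorts' outer-segment
difference was not statistically distinguishable from none.

**What passing tests do and do not show.** The phantom exercises the
geometry, contrast ordering, noise and artefact structure of real rasters,
so green tests demonstrate that the algorithms recover known truth under
those conditions. They do not validate performance on real instrument
data: real speckle is spatially correlated, real layers have texture and
pathology-dependent contrast loss, vessel shadows are oblique, and motion
artefacts exist. The phantom also has no pixel-level biological texture in
thickness itself — within an eye, thickness varies only through geometry
and segmentation noise.

## 5. Statistics

Per-eye global means are the arithmetic mean of each map over valid
pixels. The condition × age analysis is a two-way fixed-effects ANOVA with
Type II sums of squares (cells of 10–12 eyes are unbalanced; Type II
tests each main effect adjusted for the other without imposing an
ordering). Zero residual variance raises an error rather than returning
p = 1. Glucose uses the Mann-Whitney rank-sum with censored readings
entered at the 600 mg/dL ceiling and mid-ranked ties: exact enumeration of
all $\binom{n_1+n_2}{n_1}$ assignments when both groups have ≤ 8
observations, otherwise the tie-corrected normal approximation; the exact
branch matters because ceiling ties break the usual exact-distribution
shortcuts. Percent differences are $100(a-b)/b$ against the wild-type
reference and are conventionally reported to two decimals.

**Power under the study design.** With effects and between-eye SDs
matched to the reference cohort (inner-retina effect 2–4 µm against an SD
of ~4.4 µm, n = 10–12 per cell), the noncentral-t power of the condition
effect is roughly 50–70 % for IRT and ORT and ~90 % for TRT. Simulation
at these conditions reproduces exactly that: TRT thinning is detected in
>90 % of replicate cohorts, IRT/ORT in roughly half to two-thirds. This
is a property of the design being emulated, not of the implementation —
single observed p-values of 0.004–0.02 correspond to replication power
well below 90 %.

## 6. Numerical choices and degenerate inputs

* Rasterisation rounds interface depths half-up (`floor(z/pitch + 0.5)`).
* Images shallower than 20 px, with non-finite values, or with all-NaN
  columns are rejected before graph construction; empty search-region
  columns and unreachable regions raise stage-labelled errors.
* All randomness flows from one root seed through derived sub-seeds
  (cohort draws, per-eye speckle); identical seeds give bit-identical
  volumes and byte-identical pipeline CSVs. RNG state is restored after
  every generator call.
* Problem sizes in the shipped tests and acceptance script use the full
  31-B-scan raster with 96–256 A-scans and 128–160 depth pixels — enough
  to hold the full retina plus margins at 3.9 µm pitch while keeping the
  whole suite under a minute; the full 1536 × 496 geometry runs through
  the same code path via configuration.

## 7. Known limitations

* No Bruch's membrane or choroid model: OS/RPE is the posterior boundary
  throughout, so "total" retinal thickness excludes the RPE.
* Disk localisation is an input (phantom metadata or configuration), not
  detected from images.
* Operator corrections re-validate ordering but do not cascade
  re-segmentation of downstream interfaces.
* The Mann-Whitney exact branch enumerates combinations and is
  intentionally capped at 8 + 8 observations.
* Maps live on the native raster grid; no inter-B-scan interpolation or
  human-style ETDRS sectors.
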