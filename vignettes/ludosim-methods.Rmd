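---
title: "Methods: simulated 2D, 3D and hybrid dosimetry for Lu-177 therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated 2D, 3D and hybrid dosimetry for Lu-177 therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models behind `ludosim`, the parameters
that matter, the simplifications of the synthetic-data generator, and
the numerical choices made where the underlying workflow descriptions
leave the design open.

## The three dosimetry chains

All three methods estimate, per source region, a time-activity curve
(TAC) from images at roughly 24, 48 and 96 h after administration,
integrate it to a time-integrated activity (TIA), and convert TIA to
absorbed dose with a mass-adjusted dose factor.

**2D (conjugate view).** Anterior/posterior whole-body count grids are
scatter-corrected with the dual-energy-window estimate
$C_{primary} = C_{pk} - C_{sc}\,W_{pk}/W_{sc}$ (windows
208 keV ± 20 % and 187 keV ± 15 %, so $W_{pk}/W_{sc} = 41.6/28.05$),
segmented by thresholding the anterior–posterior geometric mean within
a boundary ROI, background-corrected by the per-pixel activity of a
nearby background ROI scaled to the organ pixel count, and converted to
activity by
$$A = \frac{\sqrt{C_A C_P / \bar T}\; f}{cf},\qquad
  f = \frac{\mu t/2}{\sinh(\mu t/2)},$$
with $\bar T$ the mean blank/transmission ratio over the organ mask,
$t$ the organ thickness from CT and $cf$ the counts/MBq response
measured from a known-activity vial imaged during *each* scan (which
also cancels the different scan speeds, 15 cm/min on days 1–2 vs
12 cm/min on day 4). Organs overlapping high-uptake tissue are
quantified on their visible part only and extrapolated by the
projected-area fraction, assuming homogeneous uptake; bone metastases
overlapping high-uptake tissue are excluded from planar analysis
altogether.

**3D (SPECT VOI).** Count-rate volumes are converted to activity with
the Bq/cps factor from a 6595 ml uniform-cylinder calibration scan.
Boundary VOIs drawn on the first session are propagated by rigid
translation registration; inside each boundary an iterative adaptive
threshold (threshold = α × current foreground mean, iterated to a fixed
point, α = 0.5) delineates the object; the summed activity is divided
by the recovery coefficient at the segmented volume.

**Hybrid.** The planar TAC is multiplied by
$s = A_{SPECT}(t_{anchor})/A_{planar}(t_{anchor})$ with the anchor on
day 1 by default (day 2 selectable). Ratios between time points — and
hence the fitted decay constant — are unchanged; only the absolute
scale moves to the SPECT measurement. Because rescaling by the anchor
is a multiplication of the whole curve, refitting after rescaling and
scaling the planar fit parameters by $s$ are mathematically identical
for the TIA; the package refits for uniformity.

## Kinetics and integration

Each region's TAC is fitted by weighted least squares to
$A_0 e^{-\lambda t}$ in activity space (default Poisson-like weights
$w_i = 1/\max(A_i, \varepsilon)$; uniform weights selectable). With two
points the fit is the exact interpolant; with more, a weighted
log-linear fit provides the starting point for a bounded quasi-Newton
refinement. A fitted $\lambda$ below the physical decay constant of
¹⁷⁷Lu ($\lambda_{phys} = \ln 2 / 159.528\,\mathrm{h}$) is biologically
implausible for a washout phase and is flagged; the value is kept for
diagnostics only.

The TIA uses the standard piecewise clinical scheme: constant activity
$A(t_1)$ between administration and the first scan (a rectangle —
equivalently a trapezoid with $A(0) := A(t_1)$, which reconciles the
two common phrasings of this rule); trapezoids between scans; and a
mono-exponential tail beyond the last scan governed by **physical decay
only**, $A(t_n)/\lambda_{phys}$.

Two properties of this scheme matter for interpretation, and both are
asserted by the test suite exactly as computed:

* At pure physical decay ($\lambda_{eff} = \lambda_{phys}$) the scheme
  is slightly *negatively* biased (−0.44 % for 24/48/96 h sampling):
  the rectangle underestimates the early integral by more than the
  trapezoids overestimate the convex decay, and the tail is exact.
* Under biological clearance the physical-decay tail is deliberately
  conservative and *overestimates* the TIA — by +42 % at
  $\lambda_{eff} = 5\lambda_{phys}$ for the same sampling, where the
  tail dominates. Because all three methods share the integrator, the
  method *comparison* is unaffected; absolute accuracy against an
  analytic truth is not achievable with this tail under fast clearance.
  Both alternatives are available as flags (`tail = "fit"`, floored at
  physical decay, and `first_interval = "fit"`), but the defaults
  follow the clinical scheme.

For parameter-recovery testing of the *imaging chains* the package
therefore uses a phantom whose regions decay physically only — the
digital analogue of scanning a physical phantom over three days — so
that the integrator contributes only the −0.44 % above and the
remaining error isolates projection, scatter, attenuation, blur, RC and
segmentation.

## Dose conversion

Organ masses come from the CT-surrogate label-map volumes times
configurable tissue densities (default 1.05 g/ml), matching the
clinical practice of CT-delineated masses; RC lookup, by contrast, uses
the SPECT-estimated volume. Dose factors are a pluggable table:
reference-organ entries for kidneys (310 g) and liver (1800 g) and
sphere-model entries for salivary glands and metastases. The shipped
default derives every reference S value from local electron deposition,
$$S(m) = \Delta_e \cdot 1.602\times10^{-13}\,\mathrm{J/MeV}
  \cdot 3.6\times10^{9}\,\mathrm{decays/(MBq\,h)} / m,$$
with $\Delta_e = 0.1479$ MeV per decay for ¹⁷⁷Lu and photon self-dose
fraction φ = 0 — appropriate because the ¹⁷⁷Lu absorbed dose is
β-dominated, and sufficient because the package's validation surfaces
are internal consistency (measured vs analytic dose under the *same*
table), not absolute S-value accuracy. Patient-specific mass adjustment
scales S as $m_{ref}/m$. Cross-organ photon dose is omitted by default;
the table structure accommodates externally supplied S values.

## The synthetic-data generator

`build_phantom()` voxelises organs (4.66 mm isotropic, the planar pixel
and fused SPECT voxel size) inside a water-equivalent body slab with a
per-pixel thickness map. Organ voxel sets are chosen by ranking voxels
by normalised shape distance and keeping exactly the number that
matches the requested volume, so label-map volumes are exact to one
voxel. Planar overlap is realised geometrically: a declared partner
organ is slid towards the other footprint until the shared fraction of
the smaller footprint matches the request; undeclared footprint overlap
or any 3-D collision is a configuration error.

The planar simulator is a parallel-beam line-integral model with a
single attenuation coefficient (μ = 0.11 cm⁻¹ at 208 keV) accumulated
voxel-by-voxel to each surface with midpoint path lengths — consistent
with the blank/transmission pair it also generates, which is what makes
the conjugate-view slab recovery exact to well under 1 %. Scatter is
simulated so that the dual-energy-window estimator is exact in
expectation: the scatter window receives a fixed fraction (0.3) of the
primary counts broadened by a wide (σ = 30 mm) kernel, and the
photopeak receives that image scaled by the window-width ratio. Only
the correction arithmetic is thereby exercised — this is not scatter
physics, and passing tests say nothing about model-mismatch scatter
residuals in real data.

The SPECT simulator produces post-reconstruction volumes: truth
convolved with an isotropic Gaussian PSF plus optional Poisson noise.
Reconstruction itself (OSEM, CT-based attenuation and scatter
correction) is out of scope. The default σ = 2.55 mm was calibrated
once so that a 20 ml sphere shows an uncorrected VOI recovery of 0.85,
matching the plateau of the published clinical RC table. A single
Gaussian cannot reproduce the published table's small-sphere values
(real reconstruction PSFs degrade small objects faster), so synthetic
3D quantification uses `measure_recovery_curve()` — the digital
analogue of the physical sphere-phantom RC measurement, run through the
same segmentation pipeline — while `rc_table_lu177()` ships the
published values for clinical-style lookups. Between tabulated volumes
the lookup interpolates linearly in log(volume) (RC curves are roughly
logarithmic in volume); below the smallest tabulated volume it clamps
to the smallest tabulated recovery with a warning rather than
extrapolating a steep curve downwards.

Default uptake fractions and the background concentration
(0.0035 MBq/ml) were chosen once so that the signal-to-background ratio
is ≥ 7 for the liver and > 100 for the other regions — the regime in
which contrast-recovery corrections are unnecessary — and are not
claimed to be patient-realistic in absolute terms.

**Cohort emulation.** `generate_fixture_cohort()` reproduces the
structure of a 24-patient / 65-cycle study: every patient contributes
at least one cycle, half the patients receive abdominal SPECT (kidneys,
liver), half head-and-neck SPECT (parotid and submandibular glands, one
instance per side), bone metastases occur in either group (~1.3 per
cycle; 20 % are overlap-excluded from planar analysis), and the
administered activity is 6.4 ± 1.6 GBq truncated to 3–10.9 GBq. The
cohort operates at the quantification level rather than rendering 65
full image studies: per cycle-region instance the planar measurement
carries a multiplicative lognormal bias (mean −8 % to −17 % by region
class, SD 20 % — organ overlap and background mis-specification act
multiplicatively on conjugate-view estimates and persist across a
cycle's time points) plus 4 % per-time-point noise, while SPECT carries
5 % per-time-point noise and no bias; the hybrid method shares the
anchor-day SPECT with the 3D method, as in the clinical workflow. The
bias magnitudes were set once from the scale of published
planar-vs-SPECT discrepancies in Lu-177 PSMA dosimetry and are
documented parameters, not fitted quantities. The full image chain is
exercised separately by `run_pipeline()` on single phantoms, where the
planar biases (threshold-segmentation edge losses on rounded organs,
background oversubtraction) *emerge* from the image model rather than
being injected.

What the generator does **not** emulate: collimator septal penetration
and distance-dependent resolution, patient motion, non-water tissues,
intra-organ uptake heterogeneity, bi-exponential kinetics and
early-time-point (0.5–4 h) protocols, and DICOM ingestion of scanner
output. Conclusions from passing tests therefore concern the
correctness of the correction arithmetic and the statistical machinery,
not the clinical magnitude of any bias.

## Numerical choices and degenerate inputs

* FFT-based circular convolution implements blur and dilation; the
  phantom builder keeps sources away from grid edges, and ringing below
  10⁻¹² of the maximum is clipped.
* Registration is translation-only (phantom and bed geometry make
  rotation negligible at this scale), estimated from the
  cross-correlation peak; a peak at the search-window edge warns of
  probable failure. Normalised correlation makes the shift invariant to
  global intensity scaling (decay between sessions).
* Adaptive segmentation iterates to a fixed point (≤ 100 iterations,
  error otherwise); initialisation from the boundary mean or maximum
  converges to the same fixed point on the package's fixtures, and the
  segmentation function is pluggable.
* Organ-voxel ranking breaks ties deterministically by index order, so
  phantom construction is bit-reproducible; all stochastic steps
  (counting noise, cohort sampling) derive from a single integer seed.
* Zero-activity TACs integrate to zero; all-zero differences give
  p = 1 with a warning; zero-mean dose pairs are excluded from relative
  differences with a warning; empty ROIs/VOIs and non-positive
  transmissions are errors.
* The exact signed-rank null is enumerated over all 2ⁿ sign vectors for
  n ≤ 12 (ties via average ranks); larger samples use the normal
  approximation with tie and continuity correction. The paired
  signed-rank test is the primary test because per-cycle dose estimates
  are paired; the unpaired rank-sum variant is provided as an option
  and the report states which was used.

## Problem sizes

The shipped fixtures use a 96 × 48 × 160 whole-body grid (4.66 mm
voxels) for the reference phantom, 64³ and smaller grids for slab and
sphere fixtures, three time points (24/48/96 h), and cohorts of
24 patients / 65 cycles; the cohort-ordering property is evaluated over
40 consecutive seeds. These sizes were chosen so the entire validation
suite runs on a single CPU in about a minute while every chain is
exercised end to end.

## Known limitations

* Absolute dose factors are local-deposition approximations; users
  needing phantom Monte-Carlo S values should supply their own table.
* The physical-decay tail makes absolute TIA conservative under fast
  biological clearance (see above).
* The planar background correction is the simple pixel-scaling rule;
  it mildly oversubtracts columns through the organ, which is visible
  in the slab tests at the sub-percent level with realistic
  signal-to-background ratios.
* Boundary ROIs/VOIs are fixture-generated from the label map; there is
  no interactive editing, only a deterministic offset hook.
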