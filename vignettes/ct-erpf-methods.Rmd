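---
title: "Measuring effective renal plasma flow from dynamic CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring effective renal plasma flow from dynamic CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cterpf)
```

## The measurement problem

Effective renal plasma flow (ERPF, ml/min) is the volume of plasma cleared
by the kidneys per unit time, classically measured by para-aminohippuric
acid clearance or estimated from renal scintigraphy. A short dynamic
contrast-enhanced CT acquisition offers an imaging alternative: iodinated
contrast is injected, the kidneys are scanned every 2 s for 20 s starting
8 s after injection, and the early kinetics of cortical enhancement carry
the perfusion signal. Because CT enhancement in Hounsfield units (HU) is
proportional to local iodine concentration, the kinetic analysis can be run
directly on HU curves; the unknown proportionality constant cancels in the
ratio on which the estimate is built.

`cterpf` implements the complete analysis: automatic renal-cortex
segmentation, construction of the arterial input and cortical output
functions, correction of the artery-to-parenchyma transit delay, a
per-pixel Patlak fit, hematocrit/density conversion of perfusion to ERPF,
per-kidney integration, and the agreement statistics used to validate one
method against another.

## Kinetic model

During the first pass, contrast that has been filtered by the glomeruli has
not yet left the cortex, so the cortex behaves like a trapping compartment
(the *microsphere model*). Cortical concentration decomposes into a tissue
(blood-pool) term and an accumulating glomerular term,
$C_c(t) = C_k(t) + C_g(t)$, and under pure trapping

$$C_c(t) = F \int_0^t C_a(\tau)\, d\tau,$$

with $F$ (ml/g/min) the perfusion constant and $C_a$ the arterial input.
Plotting $Y(t) = C_c(t)$ against $X(t) = \int_0^t C_a$ (the *Patlak plot*)
gives a straight line of slope $F$. The package fits that line by ordinary
least squares through three consecutive points starting at the rising edge
of the output function — early enough that the trapping assumption holds,
late enough that the signal is measurable. Internally curves are in HU and
time in seconds; the slope is multiplied by 60 in exactly one place
(`patlakSlopeToF`) to report ml/g/min.

$F$ is whole-blood flow per gram of tissue. Converting to plasma flow uses
the hematocrit in large vessels (arterial ROI, $HCT_{LV} = 0.45$) and in
the glomerular capillaries ($HCT_{SV} = 0.25$), and the tissue density
$\rho = 1.04$ g/ml (the cerebral value, adopted for kidney):

$$\mathrm{ERPF} = \frac{1 - HCT_{LV}}{1 - HCT_{SV}} \,\rho\, F
  = 0.7627\, F \ \text{(at the defaults)}.$$

The voxel plasma volume appears in both numerator and denominator of the
underlying ratio and cancels; it is never stored. Per-kidney ERPF in
ml/min is the sum over the cortex ROI of per-voxel ERPF (ml/g/min) times
the voxel mass $\rho \times$ voxel volume.

## Curve construction

*Input function.* The arterial ROI's time-density curve (TDC) is averaged
per frame; the pre-contrast *baseline* is detected as the range before the
curve starts to rise, its mean subtracted, and the result five-point
smoothed. "Started to rise" is not a self-defining phrase; the package's
rule is the first frame exceeding the initial mean plus a fraction
(`riseFraction`, default 0.10) of the peak enhancement, requiring at least
`minFrames = 3` pre-rise frames. Both knobs are exposed.

*Five-point smoothing* replaces each point by the mean of the five points
centred on it. At the series ends the window shrinks symmetrically
(3-point at the second point, passthrough at the first) so the output
keeps the input length without reflecting or extrapolating data the
scanner never acquired.

*Output function.* Three pointed cortical ROIs are averaged pointwise,
then processed like the input. `threePointRois()` reproduces this from an
automatic cortex mask by splitting it into three equal polar-angle arcs.
Both a cortical (`C_c`) and a medullary (`C_m`) variant are supported.

*Lag correction.* Contrast needs roughly 1–2 s to travel from the renal
artery into the parenchyma. Under the microsphere model the time
derivative of the tissue curve is proportional to the *delayed* arterial
curve, so the lag is estimated as the integer frame shift (0 to
`maxLagFrames`, default 3) maximizing the normalized cross-correlation
between the input function and the central-difference derivative of the
output function. The central difference is chosen deliberately: for
$C_c(t) = F\int C_a(\tau - L)$ it samples $C_a(t - L)$ *at* the frame
time, so the correlation peak sits exactly at $L/\Delta t$; one-sided
differences land half a frame off and make adjacent lags ambiguous. The
estimated lag is applied by delaying the input by whole frames before
integration. The clinical description discusses the medullary output for
this step; in this package the pipeline estimates and applies the lag on
the cortical analysis (the phantom's medulla is deliberately flat over the
dynamic window, so cortex is also the only estimable route there), and the
medullary variant remains available.

*Per-pixel maps.* Every cortex voxel's TDC is baseline-subtracted with its
own mean over the global baseline range, smoothed with the same operator,
and fitted on the same global fit window. Re-detecting the rising edge per
voxel would let single-voxel noise move the window; reusing the ROI-level
window is the robust choice. Because the fit is linear in $Y$, the mean of
per-voxel slopes over an ROI equals the slope of the ROI-mean curve, so
map-level and ROI-level analyses agree by construction.

## Automatic cortex segmentation

The cascade uses only threshold logic and the two late-phase volumes
("arterial" and "equilibrium" nephrographic frames):

1. **Bone**: threshold at 10% of the maximum HU of the first post-contrast
   dynamic frame; everything above is excluded from all later stages. The
   "first post-contrast frame" is the first frame at/after the arterial
   rise, detected on the 99.9th percentile of per-voxel enhancement over
   the mean of the first three frames — a statistic that sits inside an
   artery-sized region, so it rises as soon as the artery does.
2. **Kidney extraction**: threshold the equilibrium frame at
   `kidneyThresholdFraction` (default 0.75) of the cortical equilibrium
   HU; pixels below are removed as vessels and extrarenal tissue. The
   cortical equilibrium HU may be supplied or is estimated as the modal
   enhanced HU of the equilibrium frame (histogram mode, 5-HU bins, over
   non-bone voxels above half the non-bone maximum). The clinical
   description states the threshold is "obtained using" the cortical TDC
   maximum and the equilibrium value without a formula; the fraction rule
   is this package's documented interpretation. Components smaller than
   20 voxels are dropped as debris (8-connectivity in-plane, 26 in 3D).
3. **Left/right split**: exactly two major components are expected and
   assigned by centroid under the radiological display convention (patient
   left on image right, i.e. higher x index).
4. **Medulla removal**: within each kidney, voxels whose equilibrium HU
   strictly exceeds their arterial-phase HU are removed as medulla —
   cortex enhances early and washes out, medulla enhances late. Ties are
   retained as cortex (the removal criterion is the strict inequality).
5. **Boundary re-inclusion**: glomeruli also sit at the cortex/medulla
   boundary, so one ring (default `boundaryDilationPx = 1`) of removed
   medulla voxels adjacent to the cortex is folded back in. The extent of
   this step is not quantified in the clinical description; one ring is
   the package default.

`applyManualCorrection()` is the hook for radiologist edits (add/remove
masks; remove wins on conflict), and `coincidenceRate()` implements the
mask-agreement measure
$100\,(1 - |\text{mismatch}| / |\text{manual ROI}|)$, which is 100 for
identical masks and can go negative under gross over-segmentation.

## The digital phantom

Every stage is testable without patient data against a phantom whose
ground truth is known analytically:

* geometry: two elliptical kidneys (annular cortex, inner medulla) on a
  96×96 slice by default (1.5×1.5×5 mm voxels), a small arterial disc and
  a bright bone disc; thin 3D slabs are supported;
* arterial input: a gamma-variate first pass
  $A\,((t-t_0)/(\alpha\beta))^\alpha e^{\alpha - (t-t_0)/\beta}$ with
  onset $t_0 = 8$ s after injection start, peak amplitude 120 HU,
  $\alpha = 3$, $\beta = 1.5$ s (peak 4.5 s after onset). The clinical
  source shows only measured curves; the gamma variate is the standard
  closed-form first-pass model and its parameters are free phantom knobs
  chosen as a realistic low-dose renal bolus;
* cortical kinetics: microsphere accumulation
  $(F/60)\int_0^t C_a(\tau - \mathrm{lag})\,d\tau$ with a default 2-s lag
  and optional blood-pool term `bloodPoolFraction`$\cdot C_a(t-\mathrm{lag})$.
  The default blood-pool fraction is 0: the trapping model is the
  generative model, so the true Patlak slope of every cortex voxel equals
  the specified $F$ exactly;
* kinetics are generated on a 0.1-s grid and sampled at the frame times,
  so the estimator's quadrature error is measurable rather than baked in;
* two appended late-phase frames satisfy, by construction, the
  cortex/medulla enhancement inequalities the segmentation exploits; bone
  exceeds all soft tissue in every frame;
* optional i.i.d. Gaussian HU noise with a fixed seed.

What the phantom does *not* emulate: beam hardening, motion, partial
volume at ROI edges, realistic anatomy, dispersion of the arterial bolus,
or medullary dynamic enhancement. Passing tests therefore demonstrate the
correctness and numerical behaviour of the algorithms under the stated
kinetic model, not clinical performance on patient data.

## Numerical choices and behaviour

* **Integration**: cumulative trapezoid over frame times (second-order,
  standard for Patlak analyses).
* **Fit window**: three points starting *at* the detected rising-edge
  frame (first frame above 10% of the output peak). Whether "after the
  rising edge" includes the edge frame is ambiguous; starting at the edge
  is the default and the offset is configurable.
* **Degenerate inputs** are rejected with actionable messages: empty ROIs,
  flat curves (no rise / no lag estimate), fewer than two distinct X
  values, thresholds that empty the kidney mask, non-increasing frame
  times.
* **Units**: HU and seconds internally; ml/g/min at the fit boundary;
  ml/min after the $\rho\times$volume mass bridge. All conversions are
  centralized.
* **Convergence**: on exact sampled curves the three-point fit's
  quadrature error shrinks at least linearly in the frame interval (the
  test suite checks intervals 1, 0.5 and 0.25 s). On the full chain with
  five-point smoothing applied to both curves, the smoothing largely
  cancels between $X$ and $Y$ (both operators are linear and
  time-invariant and commute in the interior), which makes the 2-s-frame
  recovery error small (a few tenths of a percent at the defaults) but
  also means the residual is no longer pure quadrature error: it depends
  on where the discrete rising edge lands relative to the AIF peak, and
  between 2-s and 1-s frames it does not decrease monotonically. This is a
  known, documented property of the smoothed chain.
* **Right-to-left ratios** divide out the hematocrit factor and the voxel
  volume exactly; the package reports both the R/L ratio and the left
  fraction (the scintigraphy split-function convention).

## Problem sizes used by the test suite

The suite and the acceptance script run entirely on phantoms: a 96×96
single-slice grid, 11 dynamic frames plus 2 late phases, 100 noise seeds
for the stochastic recovery summary, a 19-case synthetic cohort for the
ratio-agreement statistics, and 1000-instance brute-force oracle sweeps
for the fit and agreement formulas. These sizes give stable statistics
while keeping a full run in the order of a minute.

## Known limitations

* Only NIfTI I/O is provided; DICOM series must be converted upstream.
* The kidney-extraction threshold rule and the one-ring boundary
  re-inclusion are documented interpretations of an under-specified
  clinical procedure; both are parameters.
* ERPF is reported raw; conversion between clearance conventions
  (C_PAH vs C_OIH vs C_MAG3 scalings) is left to the user.
* No GFR estimation, deconvolution-based flow, or two-compartment
  modelling.
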