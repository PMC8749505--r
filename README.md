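# cterpf

Effective renal plasma flow (ERPF) from dynamic contrast-enhanced CT by
Patlak-plot model analysis.

## What it does, and for whom

Preoperative evaluation of kidney donors (and split renal function in
general) needs a per-kidney measure of function. A short dynamic CT
acquisition — frames every 2 s for 20 s, starting 8 s after contrast
injection, plus two late nephrographic volumes — carries that signal in
the early enhancement kinetics of the renal cortex. `cterpf` is for
medical-imaging researchers who want a tested, scriptable implementation
of the full analysis chain:

* **automatic renal-cortex segmentation** by a threshold cascade (bone at
  10% of the first post-contrast frame maximum; kidneys from the
  equilibrium phase; medulla removed where equilibrium HU exceeds
  arterial-phase HU; boundary ring folded back into cortex), with a
  manual-correction hook and the coincidence-rate agreement measure;
* **input/output function construction** from ROI time–density curves:
  baseline detection and subtraction, five-point smoothing, and
  correction of the 1–2 s artery-to-parenchyma transit delay;
* **the Patlak fit**: with cortical enhancement C\_c(t) and arterial input
  C\_a(t), the microsphere (trapping) model gives
  C\_c(t) = F ∫₀ᵗ C\_a(τ) dτ, so regressing Y(t) = C\_c(t) on
  X(t) = ∫₀ᵗ C\_a gives the perfusion constant F (ml/g/min) as the slope —
  fitted on three points after the rising edge, per pixel;
* **hematocrit and density correction**:
  ERPF = (1 − HCT\_LV)/(1 − HCT\_SV) · ρ · F with HCT\_LV = 0.45,
  HCT\_SV = 0.25, ρ = 1.04 g/ml (factor 0.7627), then per-kidney
  integration (ml/min) and right-to-left ratios;
* **agreement statistics**: Pearson correlation, OLS regression, and
  Bland–Altman bias with ±1.96 SD limits of agreement, for comparing
  automatic vs manual ROIs or CT ratios vs scintigraphy uptake ratios;
* a **digital kidney phantom** with analytically known ground truth (true
  F per voxel, true lag, true labels), so every stage is testable without
  patient data.

Data in and out are NIfTI volumes with JSON sidecars (frame times, phase
tags, label codes), CSV curves, and YAML configs. A thin CLI lives at
`inst/cli/cterpf.R` (`phantom`, `segment`, `erpf`, `agree` subcommands).

## Worked example

A phantom with true perfusion 2.0 ml/g/min in the left cortex and
1.6 ml/g/min in the right (true R/L ratio 0.8), analysed end to end:

```r
library(cterpf)
res <- runPipeline(list(phantom = list(fCortexLeft = 2.0,
                                       fCortexRight = 1.6)),
                   verbose = TRUE)
#> phantom built: seed 1
#> bone threshold: 120 HU
#> kidney threshold: 148.12 HU
#> left: lag 2 s, rising edge frame 7, ROI F 1.7603 ml/g/min
#> right: lag 2 s, rising edge frame 7, ROI F 1.4082 ml/g/min
#> ERPF (ml/min): L 9.1418, R 7.3135, R/L 0.8
#> coincidence vs reference cortex: 85.882%

res$erpf
#> KidneyERPF (ml/min): left = 9.1418  right = 7.3135  total = 16.455
#>   right/left ratio = 0.8 ; left fraction = 0.55556
```

Reading the numbers: the segmentation logged the thresholds it actually
used (bone at 120 HU = 10% of the phantom's 1200-HU bone; kidneys at
148 HU = 75% of the estimated 200-HU cortical equilibrium value). The 2-s
transit lag was recovered exactly. The ROI-level slopes (1.76/1.41) are
diluted by the boundary ring of non-enhancing phantom medulla that the
cascade deliberately folds into the cortex ROI — the per-pixel map
integration is insensitive to this, so the per-kidney ERPF values land
within half a percent of the analytic truth
(F × 0.7627 × cortex mass), and their ratio is 0.8 to machine precision:
the hematocrit factor and voxel volume cancel in the ratio. The
coincidence rate of 85.9% against the ground-truth cortex reflects that
same one-ring growth; with `seg = list(boundaryDilationPx = 0)` it is
100% on the noiseless phantom.

## Documentation

The methods vignette (`vignettes/ct-erpf-methods.Rmd`) describes the
kinetic model and its assumptions, every tunable parameter with units and
defaults, what the phantom does and does not emulate, and the package's
numerical choices and known limitations.
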