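---
title: "Quantifying contrast transit in CO2 angiography: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying contrast transit in CO2 angiography: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(co2perf)
```

## The measurement problem

Endovascular therapy (EVT) of peripheral arterial disease is guided
angiographically: the operator compares blood flow through the treated
segment before and after revascularization. When carbon dioxide is used as
the contrast agent — the standard choice when iodinated contrast is
contraindicated by renal failure, allergy or hyperthyroidism — that visual
comparison is hard: CO2 is a *negative* (radiolucent) contrast agent, the
gas column fragments, and image quality fluctuates from run to run.

2D-perfusion angiography (2D-PA) replaces the visual impression with
numbers. A digital subtraction angiography (DSA) run is reduced, per
region of interest (ROI), to a *time–density curve*: the mean subtracted
contrast density inside the ROI in each frame. Each curve is summarized by
three parameters:

* **PD** (peak density) — the maximum mean density over the run;
* **TTP** (time to peak) — the time from the start of the run until that
  maximum; frame `k` is at `t = (k − 1) Δt` with `t = 0` at the first
  frame, which coincides with the start of contrast injection;
* **AUC** — the trapezoidal integral of the curve over the run, in
  density·seconds.

Absolute densities in DSA are uncalibrated (there is no Hounsfield-style
scale), so the analysis endpoints are *ratios* between a target ROI distal
to the vascular lesion (outflow) and a reference ROI proximal to it
(inflow): `TTP_outflow/TTP_inflow`, `PD_outflow/PD_inflow`,
`AUC_outflow/AUC_inflow`, computed per run and compared across the paired
pre-/post-treatment runs with an exact Wilcoxon signed-rank test. The
ratio construction cancels the unknown global density scale (exactly, for
PD and AUC) and intra-patient injection variability to first order.

## The phantom

No public angiographic dataset accompanies this kind of retrospective
study, so the package ships a synthetic phantom
([`phantom_config()`], [`simulate_run()`]) that plays the role of patient
data and, crucially, knows its own ground truth.

The phantom is a vessel given by a centerline polyline with baseline
diameter `D`, carrying a contrast bolus modelled by the standard
gamma-variate form, normalized to unit peak:

$$ g(t) = \left(\frac{t - t_0}{\alpha\beta}\right)^{\alpha}
   \exp\!\left(\alpha - \frac{t - t_0}{\beta}\right), \quad t > t_0, $$

whose mode is at `t0 + α·β`. The closed-form mode is the reason this form
was chosen: it gives an analytic TTP oracle for the recovery tests. The
bolus is advected along the centerline at `transit_speed`, so a point at
arc length `s` sees the inflow curve delayed by `s / transit_speed`.

A focal stenosis at arc-length fraction `position` has three effects:

1. **geometry** — the lumen radius narrows by a smooth cos² waist of
   compact support (±2 diameters), scaled by `residual_lumen_fraction`;
   outside the waist the lumen is exactly baseline, so ROIs placed away
   from the lesion see identical geometry pre and post;
2. **amplitude** — distal to the lesion the bolus amplitude is multiplied
   by `stenosis_attenuation` ∈ (0, 1];
3. **timing** — distal arrival is delayed by an extra `stenosis_delay`
   seconds.

When not set explicitly, attenuation and delay default to functions of
the residual lumen (`attenuation = residual_lumen_fraction`,
`delay = 3 s × (1 − residual_lumen_fraction)`), so that a tighter
stenosis always lowers distal PD/AUC and raises distal TTP — the
monotonicity the property tests assert. Transversely the density falls
off parabolically to zero at the wall, a smooth stand-in for a projected
lumen profile whose only downstream effect is sub-ROI weighting (it
cancels in the pre/post ratios, which compare identical ROI geometry).

Acquisition defaults follow a typical pelvic/femoral CO2 protocol:
7.5 frames/s, 12 s runs (10–20 s allowed), 125 µm pixels. The injection
itself (pure CO2 at constant pressure) is abstracted into the bolus input
function.

Three noise processes emulate what makes CO2 runs hard
([`phantom_noise()`]):

* additive Gaussian detector noise (`sigma_gauss`, density units);
* pulsatile modulation `1 + a·sin(2π f t)` of the vessel density,
  mirroring the arterial-pressure-synchronized fluctuation visible in
  real time–density curves (default `f` = 1.1 Hz ≈ 66 bpm);
* whole-frame dropout: with probability `dropout_prob` per frame, vessel
  density is multiplied by `dropout_factor` — the simplest mechanism that
  reproduces gaseous-bolus fragmentation as unsteady frame-to-frame
  density.

The "realistic CO2" profile used by the default study
([`run_config()`]) combines 10 % Gaussian noise (relative to bolus
amplitude), 10 % pulsatility, and 10 % dropout — roughly a 20 % combined
perturbation. These are free knobs chosen once to look plausibly hostile;
no quantitative CO2 noise characterization exists to fit them to.

What the phantom does **not** model: projection/3D physics, X-ray
spectra, injector hydraulics, and — deliberately — patient motion. Motion
in practice is handled by excluding affected runs, not by correction, so
the package records the choice but offers no registration. Passing
recovery tests on the phantom therefore demonstrates that the *analysis
chain* is correct and noise-robust, not that it is robust to motion or to
vendor-specific preprocessing of real hardware.

## Processing conventions and numerical choices

* **Subtraction** (`subtract_mask()`): default mask is the first frame
  (acquisition starts with injection, so frame 1 is pre-contrast); a
  per-pixel-extremum mask is available for runs without a clean mask
  frame. The subtraction is polarity-aware — `mask − frame` for negative
  contrast, `frame − mask` for positive — so contrast arrival is always a
  positive excursion and downstream code never branches on agent type.
  Subtracting twice is an error, never silent.
* **ROI membership**: a pixel belongs to a circular ROI iff its center
  (integer grid, 1-based `(row, col)`) lies inside the circle, boundary
  included — unambiguous and brute-force checkable.
* **ROI sizing**: ROIs must span at least 2/3 of the vessel diameter
  (`validate_roi()`, reporting rather than throwing); copying ROIs to
  the post run (`copy_roi_pair()`) is a rigid translation only — the
  point of copying is identical shape and position.
* **TTP tie-break**: first frame attaining the maximum (earliest arrival
  is the physiologically meaningful reading); an all-constant curve has
  TTP 0.
* **AUC rule**: trapezoid, scaled by the frame interval, hence
  acquisition-rate invariant. Only "integration of successive values" is
  specified by the technique; trapezoid is second-order accurate and, at
  7.5 fps on the phantom bolus, within 1 % of adaptive quadrature of the
  analytic curve (asserted in the tests). The ratio endpoints are
  invariant to the rectangle-vs-trapezoid choice up to this error.
* **No smoothing by default**: pulsatile fluctuation is part of the
  signal; a centered moving average is available but off
  (`compute_params(smooth_width = )`).
* **TTP origin caveat**: TTP is measured from the start of the run. The
  TTP ratio is *not* invariant to prepending frames — the test suite
  asserts this sensitivity on purpose, so a convention drift cannot pass
  silently. Whether vendor software measures TTP from injection, arrival
  or bolus detection is generally undocumented; with a shared origin the
  PD and AUC ratios are unaffected either way.
* **Zero inflow parameters** abort ratio computation (a failed injection
  should fail loudly, not return infinity).
* **Wilcoxon**: zero differences are dropped (Wilcoxon's original rule)
  and counted; mid-ranks for ties; `W = min(W⁺, W⁻)`. For ≤ 25 nonzero
  pairs the two-sided p is exact — the null distribution of `W⁺` over all
  `2^m` sign assignments, computed by subset-sum convolution over doubled
  ranks (integers even with mid-ranks), with
  `p = min(1, 2·min(P(W⁺ ≤ w), P(W⁺ ≥ w)))`. Ten concordant tie-free
  pairs give exactly `2/1024 ≈ 0.00195`, i.e. the familiar rounded 0.002.
  Above 25 pairs a flagged normal approximation with tie and continuity
  correction takes over. Percent changes are rounded to integers for
  report parity; full precision is kept in machine output.
* **File formats**: multipage TIFF plus a JSON sidecar (the sidecar is
  mandatory on read — a stack without a frame interval cannot support
  TTP), or an exact serialized array archive. Integer-valued stacks are
  stored in TIFF as 16-bit and round-trip exactly; general stacks are
  scaled 32-bit float, i.e. single precision. DICOM export is out of
  scope.

## The end-to-end study and problem sizes

`run_end_to_end(run_config())` mirrors a small paired revascularization
study: 10 interventions (seeds 0–9), each a pre run with distal PD
attenuation set-point 0.44 and a post run at 0.80 with the stenosis
relaxed to a residual lumen ≥ 0.7 — the "< 30 % residual stenosis"
technical-success criterion — under the combined noise profile. Frames
are 64 × 192 px over 12 s at 7.5 fps: sizes chosen so the full study,
including parametric maps, runs in seconds while leaving dozens of pixels
per ROI and ninety frames per curve, which is where the statistical
behaviour of the estimators lives. The recovery tests require the mean
recovered PD ratio within ±0.10 of each set-point and the post > pre
ordering in at least 9 of 10 pairs; the observed recovery is typically
within ±0.01, with the residual bias dominated by pulsatile peak-picking
(which largely cancels between inflow and outflow).

A note on the AUC ratio: with a finite run, a bolus arriving late distal
to a severe stenosis is integrated over a truncated window, so the
noiseless AUC ratio is slightly *below* the amplitude attenuation factor.
The ground-truth object computes its expected AUC by quadrature over the
same finite window, so oracle and measurement share the convention.

## Known limitations

* Equivalence with any vendor's proprietary 2D-PA implementation is not
  claimed — only with the stated operational definitions of TTP, PD, AUC
  and their ratios.
* The phantom's ROIs are placed from ground-truth geometry; automatic
  vessel-width estimation and lesion detection are out of scope, as is
  any interactive ROI tool.
* No multiplicity correction is applied across the three endpoints,
  matching standard practice for a three-row treatment table at n = 10.
* The exact-p convention (two-sided, doubled one-tail, capped at 1) is
  one of several in circulation; it is stated here so results are
  reproducible, not asserted as the only defensible choice.
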