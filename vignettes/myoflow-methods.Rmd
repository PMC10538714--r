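---
title: "Models, calibration and design choices in myoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, calibration and design choices in myoflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoflow)
```

# Scope

`myoflow` implements a two-modality quantification of resting myocardial
blood flow (MBF): a one-tissue-compartment kinetic analysis of dynamic
ammonia PET, and a dual-bolus Tofts analysis of dynamic contrast-enhanced
MRI, plus the supporting machinery a longitudinal cardiac study needs —
frame binning, 16-segment regional aggregation, dual-bolus quality
control, an LGE enhancement threshold, linear-quadratic dose equivalence,
and a nonparametric statistics battery. A synthetic-data generator
emulating a five-animal, six-visit design makes every stage testable
without image data. This vignette records the models, the tunable
parameters, and the design decisions that were genuinely open.

# Kinetic models and their shared numerical core

## One-tissue compartment model (PET)

Tissue activity is modelled as

$$C_t(t) = K_1 \int_0^t C_{LV}(\tau)\, e^{-k_2 (t-\tau)}\, d\tau$$

with uptake $K_1$ (ml/min/g) and clearance $k_2$ (min$^{-1}$). Times are
kept in seconds throughout; the per-minute rates are divided by 60 at the
model boundary. The measured uptake constant is related to flow by the
Renkin–Crone relation $K_1 = (1 - a e^{-b\,\mathrm{MBF}})\,\mathrm{MBF}$.
The defaults are $a = 0$, $b = 0$ — the identity $K_1 = \mathrm{MBF}$,
which is the standard operating approximation for ammonia at resting
canine flows (extraction is essentially complete below 6 ml/min/g). The
dog-specific $(a, b)$ calibration is not published with the study this
design follows, so non-zero values are accepted via
`RenkinCroneParams(a, b)` and inverted by bisection on
$[K_1, K_1/(1-a)]$ to $10^{-9}$ (the relation is strictly increasing, so
the root is unique).

## Tofts model (DCE-MRI)

$$C_t(t - t_0) = K^{trans} \int_0^{t} C_p(\tau)\,
  e^{-k_{ep}(t - t_0 - \tau)}\, d\tau$$

with $K^{trans}$ (ml/min/g), efflux rate $k_{ep}$ (min$^{-1}$) and bolus
arrival delay $t_0$ (s). $k_{ep}$ is fitted freely rather than
constrained to $K^{trans}/v_e$: the equation treats it as an independent
flux rate constant. Flow follows from the extraction-fraction relation
$\mathrm{MBF} = K^{trans}/EF$ with $EF = 0.5$, the reference value for
Gd-DTPA in normal canine myocardium.

## Exact exponential convolution

Both models share one engine: the input curve is interpolated piecewise
linearly and the convolution with $e^{-k s}$ is integrated in closed form
on every linear segment, via the recurrence
$I(t_{j+1}) = I(t_j) e^{-k\Delta} + c_j \frac{1-e^{-k\Delta}}{k} +
m_j\left(\frac{\Delta}{k} - \frac{1-e^{-k\Delta}}{k^2}\right)$,
with series fallbacks for $k\Delta \to 0$ and an exponential-rescaling
vectorization that is safe for the bounded rates used here. The result is
exact for the interpolant, so accuracy is limited only by the input
sampling; the test suite checks agreement with brute-force quadrature to
0.1% on gamma-variate inputs, and that the Tofts model with $t_0 = 0$
equals the one-tissue model to machine precision.

## Fitting

Both fits minimize (weighted) squared residuals with box-constrained
L-BFGS-B from a multi-start grid, $K_1 \in \{0.2, 0.8, 2.0\}$ ml/min/g
$\times$ $k_2 \in \{0.1, 0.5, 2.0\}$ min$^{-1}$ (and the same grid for
$K^{trans}, k_{ep}$), which brackets the physiologic range and avoids
local minima; $t_0$ is initialized at the plasma-curve onset and bounded
within $\pm 10$ s of it. PET weights default to the frame durations (a
weighted scheme is standard but the study's exact weights are not
printed; variance-based weights can be passed explicitly). Only frames
with timestamps inside the 4-minute window are fitted. An identically
zero tissue curve short-circuits to $K_1 = 0$ (or $K^{trans} = 0$) with a
warning; failure of every start raises an unidentifiable-input error.

Two discretization choices matter for unbiased recovery:

* **Frame averaging.** Binned PET data are frame averages, not point
  samples. When frame durations are present the fit averages the model
  within each frame (Simpson rule, 5 nodes/frame); evaluating at frame
  midpoints instead biases the long 60 s frame visibly.
* **Arterial input sampling.** Fitting against a piecewise-linear
  interpolant of the frame-binned LV curve flattens the bolus peak and
  inflates $K_1$ by a few percent. `simulatePET()` therefore also returns
  `lvRef`, the finely sampled noiseless input, which the pipeline uses;
  fitting against the binned LV is possible and the bias is then part of
  the realistic error budget.

# Dual-bolus AIF construction and QC

The low-dose arterial curve is baseline-subtracted (mean of its
pre-injection window), magnified by the bolus volume ratio (default 10),
time-shifted by the nominal inter-bolus delay (default 25 s) so its onset
coincides with the high-dose injection, and resampled onto the high-dose
window. "Normalization" is implemented as exactly this baseline
subtraction plus alignment to the high-dose injection time; the shift
convention is configurable (`shift = "none"`) for acquisitions whose
clocks are already aligned. Outside the shifted small-curve support the
stitched AIF is zero: with the default bolus geometry (gamma-variate,
shape 3, time-to-peak 4 s, 17 s of coverage after injection) the
truncated first-pass tail carries well under 1% of the bolus mass.
Bolus onset detection uses baseline mean + 5 baseline SDs, configurable.
The hematocrit correction $C_p = C_b/(1 - 0.45)$ applies to the stitched
arterial curve only — it converts blood to plasma concentration and has
no business on tissue curves.

Two QC detectors encode the study's exclusion rules as explicit
surrogates for what was originally a visual call:

* **Residual contrast** — fails when (pre-high-dose baseline −
  pre-low-dose baseline) / low-dose peak exceeds 0.1. The 0.1 is an
  invented, logged default; the comparison is a strict inequality, so a
  metric exactly at the threshold passes.
* **Reversed order** — fails when the first-pass peak exceeds the
  second-pass peak; equal peaks pass with a warning.

Both decisions are scale-invariant. An acquisition is excluded iff any
check fails (detector errors count as failures).

# LGE, dose equivalence, RPP

Focal enhancement uses the signal-threshold-versus-reference-myocardium
rule: pixels above reference mean + 5 SD. The threshold is one-sided
(enhancement only), which is how the $\pm$5 SD rule is used in its
scar-detection role. Dose equivalence uses the linear-quadratic
biologically effective dose $BED = nd(1 + d/(\alpha/\beta))$ with
$\alpha/\beta = 2.5$ Gy and solves $d^*(1 + d^*/(\alpha/\beta)) = BED$
for the single-fraction equivalent; the 30 Gy / 25 fraction scheme is
taken as 1.2 Gy per fraction (only the totals are printed, so per-fraction
dose is total/n), giving $d^* \approx 9.36$ Gy, i.e. the "~9 Gy" single
fraction. RPP is heart rate × systolic pressure with missing values
propagated.

# The synthetic cohort: what it emulates and how it is calibrated

`simulateCohort()` draws a long-format table (animal × visit × territory
× modality). Its defaults are the study conditions:

| parameter | default | why |
|---|---|---|
| animals, visits | 5; baseline, 1wk, 1mo, 3mo, 6mo, 12mo | the study design |
| baseline MBF | 0.9 ± 0.1 ml/min/g | typical resting canine flow (not printed in the study; configurable) |
| follow-up multipliers | 1.25, 1.25, 1.0, 1.3, 1.35 | qualitative trajectory: flow elevated at every follow-up except the transient 3-month return to baseline (multiplier exactly 1); invented calibration knobs |
| SUV | 1.1 ± 0.03 baseline, 2.6 ± 0.19 follow-up | the persistent inflammation signal |
| MBF–SUV correlation target | 0.5 | the reported whole-myocardium association |
| RPP | 9600 bpm·mmHg, CV 10%, constant mean | unchanged oxygen demand across visits |
| EF, Hct | 0.5, 0.45 | the conversion constants |

MBF is baseline mean × visit multiplier × lognormal noise; SUV is drawn
per animal-visit; the DCE modality shares the NH3 ground truth with an
unbiased 5% lognormal measurement noise (`dceNoiseCv`, added so the
paired modality comparison is nondegenerate; set it to 0 for identical
columns). Heart rate and systolic pressure are lognormal with
visit-constant means.

**Correlation calibration.** The configured `mbfSuvCorrelation` is the
*target record-level Pearson correlation* between SUV and
whole-myocardium MBF. The systematic time profiles already induce a
substantial correlation on their own (both MBF and SUV are elevated at
follow-up), so the generator moment-matches: it computes the
between-visit covariance implied by the configured profiles and solves
for the latent Gaussian noise correlation that makes the expected overall
correlation equal the target (normal approximation of the lognormal
noise; CV ≈ 0.11 at defaults, where the approximation error is
negligible). If the profiles alone exceed the target, the latent
correlation is clamped to ±1 with a warning. With a time-flat
configuration the two notions coincide, which is how the
zero-correlation property is tested.

**What the generator does not emulate:** MR signal saturation and T1
relaxivity (signal is taken proportional to concentration — the
dual-bolus premise itself), Rician magnitude noise (curves are ROI means,
where Gaussian is a good approximation), radioactive decay (generation
and fitting are both decay-free; a correction hook exists but defaults
off), spillover and partial-volume effects, and physiologic
recirculation beyond a simple delayed gamma bump. Passing tests therefore
demonstrate correctness of the quantification chain under its own model
assumptions, not robustness to every acquisition artifact of real data.

# The 16-segment model

Segments 1–16 map to coronary territories LAD, LCX and BOTH (the region
potentially supplied by both arteries). The published layout is pictorial
only, so the shipped default
(`inst/extdata/segment_territories.json`) is an explicit approximation
following the usual anterior/anteroseptal vs lateral/inferolateral
division; it is an editable JSON file and `readSegmentModel()` accepts
any mapping with all three territories non-empty. Territory aggregation
is an unweighted mean over member segments — per-segment areas are not
available, and the choice is recorded here precisely because it is a
choice.

Frame timestamps are midpoints by default (`timestamp = "start"` is
available); events on a frame boundary belong to the later frame, and
events beyond the schedule are dropped.

# Statistics

The battery mirrors the study's analysis: Kruskal–Wallis across the six
visits (tie-corrected, via `stats::kruskal.test`), two-sided Mann–Whitney
of each follow-up against baseline — deliberately unpaired, replicating
the study's specification even though the animals are the same; a
documented substitution of a paired test would change the null — with the
exact null distribution whenever both groups have $n \le 8$ (the study
has $n = 5$) and no ties, Pearson correlation of MBF with SUV per
territory, and a paired t-test between the two modality's MBF estimates
with QC-excluded records dropped pairwise. No multiple-testing correction
is applied by default (none is described in the study); `holm = TRUE`
enables one. Degenerate cells (insufficient n, zero variance) are
reported as missing with a reason, never as errors.

# Pipeline and reproducibility

`runPipeline()` chains simulate → fit PET → fit DCE → QC → aggregate →
statistics → report. Everything derives from one seed; per-visit seeds
are derived deterministically, outputs are written without timestamps,
and two runs with the same configuration are byte-identical. In
curve-level mode the tabular DCE measurement noise is disabled — the DCE
error then comes from the curve fits themselves — and per-visit failures
are recorded and skipped rather than aborting the run.

Problem sizes used by the test suite (chosen as sensible Monte-Carlo
sizes for the properties being checked): 100 seeded replicates for the
5%-noise parameter-recovery studies, 200 cohorts for the calibration
means, 1000 replicates for the Kruskal–Wallis type-I error and the QC
false-exclusion rate, and single-animal noise-free runs for end-to-end
recovery.

# Known limitations

* The territory map is an approximation of a pictorial source.
* The exact weighting scheme of the original weighted least squares and
  the dog-specific Renkin–Crone constants are not published; defaults
  implement the stated approximations and both are configurable.
* QC thresholds are explicit surrogates for visual exclusion calls.
* The generator's follow-up multipliers are qualitative: the study's
  per-visit flow values exist only as figures, and no attempt is made to
  match figure heights.
* Real-data effects listed above (saturation, decay, spillover, motion)
  are out of scope by design.
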