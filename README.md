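# myoflow

Quantification of **resting myocardial blood flow (MBF)** from two
simultaneously acquired modalities on a hybrid PET/MR scanner:

* **dynamic ammonia-13 PET** — a one-tissue-compartment tracer kinetic
  model fitted to the first 4 minutes of frame-binned list-mode data, with
  the uptake constant converted to flow through the Renkin–Crone relation;
* **dual-bolus dynamic contrast-enhanced MRI (DCE-MRI)** — a low-dose
  (0.4 ml) arterial bolus magnified by the 1:10 dose ratio to stand in for
  the saturated high-dose (4 ml) arterial input, Tofts-model deconvolution
  of the high-dose tissue curves, and conversion of K<sup>trans</sup> to
  flow through the contrast extraction fraction.

The package is aimed at researchers analysing longitudinal cardiac
perfusion studies (for example after focal cardiac irradiation in a canine
model) who need a tested, reproducible implementation of the
quantification chain, its quality-control rules, the regional (16-segment,
coronary-territory) aggregation, the linear-quadratic dose-equivalence
calculation, and the nonparametric longitudinal statistics — together with
a synthetic-data generator that emulates a five-animal, six-timepoint
study design so every stage can be exercised end to end without any
animal data.

## Models

**PET.** Tissue activity is the arterial (LV blood-pool) curve convolved
with the uptake/clearance kernel,

> C<sub>t</sub>(t) = K₁ ∫₀ᵗ C<sub>LV</sub>(τ) e^(−k₂ (t−τ)) dτ,

with K₁ (ml/min/g) and k₂ (min⁻¹) estimated by weighted least squares
(weights = frame durations) over frames within the 4-minute window, and

> K₁ = (1 − a·e^(−b·MBF)) · MBF  (Renkin–Crone; a = 0 by default, the
> resting-flow approximation where extraction ≈ 1 below 6 ml/min/g).

**DCE-MRI.** The small-bolus arterial curve is baseline-subtracted,
magnified by the bolus ratio (10), shifted by the inter-bolus delay
(25 s) and truncated onto the high-dose window; plasma concentration is
C<sub>p</sub> = C<sub>b</sub>/(1 − Hct) with Hct = 0.45; tissue curves
follow the Tofts model

> C<sub>t</sub>(t − t₀) = K<sup>trans</sup> ∫₀ᵗ C<sub>p</sub>(τ)
> e^(−k<sub>ep</sub>(t − t₀ − τ)) dτ,

and MBF = K<sup>trans</sup>/EF with extraction fraction EF = 0.5.

Both convolutions share one exact piecewise-linear exponential-convolution
engine, so the Tofts and one-tissue forward models coincide for t₀ = 0.

Also included: dual-bolus QC detectors (residual contrast before the
high-dose injection; reversed injection order), the LGE focal-enhancement
threshold (reference mean + 5 SD), BED-based single-fraction dose
equivalence (α/β = 2.5 Gy), the rate–pressure product, and a statistics
battery (Kruskal–Wallis across visits, exact small-sample Mann–Whitney
versus baseline, Pearson MBF–SUV correlation, paired PET-vs-DCE test).

## Worked example

```r
library(myoflow)

## PET: simulate a list-mode acquisition (100k events) and fit it
sim <- simulatePET(params = OneTissueParams(K1 = 0.8, k2 = 0.4),
                   totalEvents = 1e5, seed = 42)
fitOneTissue(sim$tissue, sim$lvRef)
#> One-tissue-compartment fit
#>   K1 = 0.8085 ml/min/g, k2 = 0.4059 /min
#>   MBF = 0.8085 ml/min/g (Renkin-Crone a = 0, b = 0)
#>   weighted RSS = 0.5211 over window 0-240 s

## DCE: dual-bolus acquisition with noise, full quantification
acq <- simulateDualBolus(noiseSd = 0.1, seed = 42)
quantifyDCE(acq)$fits$global
#> Tofts model fit
#>   Ktrans = 0.4712 ml/min/g, kep = 0.7706 /min, t0 = 0.00 s
#>   MBF = 0.9425 ml/min/g (extraction fraction 0.50)
#>   RSS = 1.32

## the ~9 Gy single-fraction equivalent of 30 Gy in 25 fractions
equivalentSingleFractionDose(DoseScheme(25, 30 / 25, alphaBeta = 2.5))
#> [1] 9.359548

## longitudinal statistics on a synthetic 5-animal cohort
coh <- simulateCohort(cohortSimConfig(seed = 1))
rep <- buildStatReport(coh)
rep$contrasts[rep$contrasts$territory == "GLOBAL" &
              rep$contrasts$modality == "NH3", ]
#>    territory modality timepoint  U          p reason
#> 31    GLOBAL      NH3       1wk 24 0.01587302   <NA>
#> 32    GLOBAL      NH3       1mo 22 0.05555556   <NA>
#> 33    GLOBAL      NH3       3mo 14 0.84126984   <NA>
#> 34    GLOBAL      NH3       6mo 23 0.03174603   <NA>
#> 35    GLOBAL      NH3      12mo 24 0.01587302   <NA>
```

The PET fit recovers the generating K₁ = 0.8 ml/min/g to ~1% at 10⁵
events; the DCE chain recovers K<sup>trans</sup> = 0.45 ml/min/g (true
flow 0.9 ml/min/g at EF 0.5) within a few percent at this noise level;
and the cohort contrasts show the study's signature pattern — flow
elevated at every follow-up visit except the transient return to baseline
at 3 months (p = 0.84 here).

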