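# ribdose

Dose–volume analysis of radiation-induced rib fracture (RIRF) after
stereotactic ablative radiotherapy (SABR) of lung tumors.

Rib fracture is the characteristic late chest-wall toxicity of SABR: a few
very large fractions put small volumes of rib under biologically extreme
dose. `ribdose` implements the full dosimetric risk-analysis pipeline used
to find *which* rib dose–volume metric predicts fracture and *where* its
clinical cutoff lies, together with a seeded synthetic cohort generator so
that every stage is testable end-to-end without patient data. It is aimed
at radiotherapy outcome modellers and medical physicists.

## What it computes

* **EQD2 conversion.** Physical dose `D` delivered in `n` fractions
  (`d = D/n` per fraction) is converted to the equivalent dose in 2 Gy
  fractions under the linear-quadratic model,

  `EQD2 = D * (d + α/β) / (2 + α/β)`,

  with `α/β = 3` Gy for late-responding bone. Conversion is voxel-wise;
  multi-course doses are summed voxel-wise on a common frame, and lesions
  are merged when any rib receives ≥ 10 Gy EQD2 from both.
* **Rib DVH metrics.** Cumulative absolute-volume DVHs of the union of all
  ribs receiving ≥ 10 Gy EQD2 yield `D_max`, the `D_V` family
  (V = 0.1–5 cc in 0.1 cc steps, 6–10 cc in 1 cc steps) and the `V_D`
  family (D = 50–300 Gy EQD2 in 10 Gy steps).
* **Predictor and cutoff selection.** Every grid metric is scored against
  the fracture outcome by the empirical ROC; the AUC equals the
  Mann–Whitney concordance probability (ties at ½) and its p-value uses
  the tie-corrected normal approximation. The AUC-maximising `D_V` and
  `V_D` are selected and dichotomised at the Youden-optimal
  (max sensitivity + specificity − 1) cutoff.
* **Time-to-fracture modelling.** Kaplan–Meier actuarial incidence,
  two-group log-rank screening of clinical and dosimetric factors, a
  collinearity screen (one representative per cluster of mutually
  associated factors), and a multivariate Cox proportional-hazards model
  (Breslow ties).
* **4D dose accumulation.** A 10-phase respiratory emulation (rigid
  tumor/fiducial motion over a periodic trace, static ribs): per-phase
  dose, translation-only fiducial registration, phase-weighted
  accumulation, and paired t-test comparison of 3D planning vs 4D
  accumulated rib metrics.
* **Synthetic cohort.** 49 lesions in 39 patients by default: 45–66 Gy in
  3–6 fractions prescribed to the 80% isodose line, log-normal GTV volumes
  (median 5.90 cc), rib–tumor distances with median 0.25 cm including an
  abutting/invading component at 0.00 cm, and Weibull time-to-fracture
  outcomes whose log-hazard rises with `D_4.6cc` above a 140 Gy EQD2
  threshold, censored at a median follow-up of 26.7 months.

## Worked example

```r
library(ribdose)

cfg <- cohort_config(seed = 20260925L)   # 49 lesions / 39 patients
co  <- simulate_cohort(cfg)              # dose grids -> metrics -> outcomes
fit <- rib_fracture_analysis(cohort_table(co), entry = "p_gated")
fit
```

```
Rib fracture dosimetric risk analysis
  49 lesions, 13 fracture events (crude 26.5%)
  actuarial incidence: 13.3% at 2 years, 31.2% at 3 years
  best D_V : D_10cc (AUC 0.739, p = 0.0112), cutoff 44.8 Gy EQD2
  best V_D : V_50 (AUC 0.720, p = 0.0196), cutoff 8.41 cc
  retained after collinearity screen: sex_male, multiple_treatment, copd, D_10cc
  multivariate Cox (p_gated entry):
    term coef   hr    se    z      p
1 D_10cc 1.42 4.15 0.663 2.15 0.0316
```

The crude fraction and 2-year actuarial incidence describe how often and
how fast fractures occur; the selection block names the most
discriminative dose–volume metric in each family with its AUC and Youden
cutoff; the Cox table gives the adjusted hazard ratio of the retained
dosimetric factor. At n = 49 the *identity* of the winning grid point is
sampling-noisy — that is a property of small cohorts, and the test suite
therefore verifies metric/cutoff recovery on 2000-lesion cohorts, where
the planted `D_4.6cc` / 140 Gy signal is recovered to ±0.5 cc and ±10 Gy.

A single closed-form anchor worth knowing: `eqd2(41.7, 3)` ≈ 141 Gy, i.e.
a 140 Gy EQD2 rib cutoff corresponds to 41.7 Gy in 3 fractions.

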