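# afboost

ECG beat classification and P-wave markers for predicting new-onset
atrial fibrillation (AF) after coronary artery bypass grafting (CABG).

Postoperative AF is common after CABG and is foreshadowed by two kinds of
ECG evidence: arrhythmic beats (premature ventricular contractions, PVCs)
on continuous monitoring, and P-wave morphology on the 12-lead ECG — the
dispersion markers Pmax and Pmin (longest and shortest per-lead P-wave
duration) and the P terminal force in lead V1, PTFV1 = −(width s ×
depth mm) of the terminal negative P deflection at the 25 mm/s, 10 mm/mV
calibration. `afboost` implements the full chain for researchers who want
every stage testable against known ground truth:

* **`synth` / generators** — seeded sum-of-Gaussians 12-lead ECG with
  exact fiducials (true P duration = 2kσ_P, k = 2.5), PVC and AF rhythms,
  baseline wander / 55 Hz interference / white noise; plus two-group
  patient cohorts with configurable marker separations and the covariate
  prevalences of a 52/54-patient post-CABG cohort.
* **`preprocess`** — zero-phase 55 Hz notch (≥ 30 dB), median/moving-average
  baseline correction, 40 Hz low-pass.
* **`delineate`** — quadratic-spline wavelet R detection (modulus-maxima
  pairs), P/QRS/T fiducials by equipotential-line intersection, per-lead
  P durations, Pmax/Pmin/PTFV1.
* **`classify`** — Gentle AdaBoost from scratch: regression stumps
  minimising weighted squared error, the canonical reweighting loop
  `W_i ← W_i exp(−Y_i f_n(X_i))`, prediction `sign(Σ f_n)`; a plain
  back-propagation network (10→10→2, lr 0.2, target MSE 0.002) as
  comparator; a 1242-beat train/test exchange benchmark.
* **`cohort_stats`** — cohort summaries, t / chi-square tests, IRLS
  logistic regression with Wald odds ratios and 95% CIs, ROC/AUC with
  Youden-index cutoffs, sensitivity/specificity/PPV/NPV.

## Worked example

The numbered scripts under `analysis/` run the study end to end and write
their tables to `results/`. Running them in order prints, among other
things:

```
$ Rscript analysis/03_benchmark.R
<benchmark_report> median test accuracy: Gentle AdaBoost 0.977, back-propagation 0.934 (margin 0.043)
Gentle AdaBoost leads back-propagation by 4.3 accuracy points (median over 20 runs).

$ Rscript analysis/04_cohort_analysis.R
Marker performance at the Youden-optimal cutoff:
  pmax   AUC 0.896, cutoff >= 123.2, sens 86.5%, spec 81.5%, PPV 81.8%, NPV 86.3%
  pmin   AUC 0.810, cutoff >= 105.8, sens 71.2%, spec 75.9%, PPV 74.0%, NPV 73.2%
  ptfv1  AUC 0.684, cutoff <= -0.01829, sens 48.1%, spec 85.2%, PPV 75.8%, NPV 63.0%

End-to-end (signal -> Pmax): AUC 0.930, Youden cutoff 119.4 ms (group means 127.4 / 107.9 ms).
```

Reading: on the synthetic 1242-beat pool (254 PVCs), boosted stumps
generalise better than the plain back-propagation network under the
621/621 exchange protocol. On the synthetic cohort, Pmax discriminates
future AF best (AUC ≈ 0.9) with a cutoff near 123 ms — a patient at or
above the cutoff is called AF-prone with the listed sensitivity and
specificity — while PTFV1 is a weaker marker whose negative cutoff means
"a more negative terminal force predicts AF". The end-to-end line runs
the whole signal chain (simulate → preprocess → delineate → measure) per
patient before the ROC, showing the pipeline preserves a 20 ms group
difference in true Pmax.

A minimal interactive session:

```r
library(afboost)
sim <- generate_record(30, seed = 1)          # 12-lead ECG + ground truth
pre <- preprocess_record(sim$record)
pm  <- measure_p_metrics(pre)                 # Pmax, Pmin, PTFV1
pm
#> <p_wave_metrics> Pmax 100.0 ms, Pmin 74.1 ms, PTFV1 -0.0117 mm*s
```

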