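# panflux

Kinetic modeling of hyperpolarized [1-¹³C]pyruvate metabolic flux for
early detection of pancreatic premalignant lesions.

## The problem

Pancreatic intraepithelial neoplasias (PanINs) — the precursor lesions of
pancreatic ductal adenocarcinoma — are invisible to conventional imaging.
Dynamic hyperpolarized ¹³C magnetic resonance spectroscopy (HP-MRS) can
watch an injected [1-¹³C]pyruvate bolus being converted to lactate (via
LDH) and alanine (via ALT) in real time. As lesions progress, LDH activity
rises and ALT activity falls, so the apparent conversion rate constants
k_PL and k_PA, and the model-free area ratios Lac/Pyr and Ala/Pyr, shift in
opposite directions and act as imaging biomarkers.

`panflux` implements the full analysis chain for such experiments, plus a
synthetic-cohort generator with known ground truth so every stage can be
validated by parameter recovery:

* **Forward model** — unidirectional three-pool exchange under RF
  sampling. Between excitations,

  dP/dt = −(k_PL + k_PA + R₁P)·P,  dL/dt = k_PL·P − R₁L·L,
  dA/dt = k_PA·P − R₁A·A,

  each transient observes sin θ · Mz and costs a factor cos θ of
  z-magnetization. RF loss folds into effective rates
  R̃₁ = R₁ − ln(cos θ)/TR, giving a closed form that matches the
  discrete-event simulation to machine precision.
* **Spectral processing** — exponential apodization, Fourier transform,
  automatic phasing, chemical-shift referencing against a ¹³C-urea
  phantom, and trapezoidal peak integration per transient.
* **Kinetic fitting** — two-stage bounded Levenberg–Marquardt: pyruvate
  amplitude and effective decay first, then k_PL and k_PA per product
  channel with standard errors from the Jacobian (joint fit available).
* **Flux ratios** — ratio-over-sum metrics
  Lac/Pyr = AUC_lac/(AUC_lac + AUC_pyr) (and Ala/Pyr analogously), and ex
  vivo ¹H-NMR quantification of alanine/lactate methyl doublets against a
  TMSP internal standard.
* **Group statistics** — mean ± SD summaries, Welch unequal-variance
  t-tests, and monotone-trend checks across disease stages.

## Worked example

```r
library(panflux)

acq <- acq_params()                     # 90 transients, TR 2 s, 12 deg
coh <- generate_cohort(default_cohort_config(), acq)
rep <- analyze_cohort(coh, group_order = c("control", "kc20", "kc30"))
print(rep)
```

```
In vivo flux report (group mean +/- SD)
  control  Ala/Pyr 0.175 +/- 0.012  Lac/Pyr 0.214 +/- 0.009  kPA 0.0095 +/- 0.0006  kPL 0.0123 +/- 0.0006
  kc20     Ala/Pyr 0.152 +/- 0.010  Lac/Pyr 0.322 +/- 0.008  kPA 0.0076 +/- 0.0007  kPL 0.0223 +/- 0.0008
  kc30     Ala/Pyr 0.118 +/- 0.009  Lac/Pyr 0.383 +/- 0.004  kPA 0.0055 +/- 0.0005  kPL 0.0294 +/- 0.0007
Trends along control -> kc20 -> kc30
  ala_pyr    decreasing monotone (means: 0.1752, 0.1517, 0.1177)
  lac_pyr    increasing monotone (means: 0.2138, 0.3223, 0.3834)
  k_pa_per_s decreasing monotone (means: 0.009494, 0.007587, 0.005543)
  k_pl_per_s increasing monotone (means: 0.01232, 0.02235, 0.02944)
  ala_lac    decreasing monotone (means: 0.8995, 0.5559, 0.3085)
```

Thirty synthetic subjects (three groups of ten) are simulated from the
published group-mean rate constants, fitted per subject, and summarized.
The fitted kPA/kPL group means recover the generating truth, and all five
biomarker trends move in the direction reported for PanIN progression.
`write_cohort()`/`write_report()` persist cohorts and reports as
CSV/JSON; `fit_kinetics()` on a single `metabolite_series` gives one
subject's fit with standard errors, and `plot()` overlays fit and data.

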