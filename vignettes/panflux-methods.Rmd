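---
title: "Kinetic modeling of hyperpolarized pyruvate flux: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modeling of hyperpolarized pyruvate flux: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panflux)
```

## The model

After a bolus of hyperpolarized [1-¹³C]pyruvate, the labeled carbon is
exchanged into lactate (LDH) and alanine (ALT). At the signal-to-noise
and time scales of an in vivo dynamic acquisition the back-reactions are
not identifiable, so `panflux` uses the standard unidirectional
(precursor–product) three-pool model. Between RF excitations the
z-magnetizations evolve as

$$\frac{dP}{dt} = -(k_{PL} + k_{PA} + R_{1P})P, \qquad
  \frac{dL}{dt} = k_{PL}P - R_{1L}L, \qquad
  \frac{dA}{dt} = k_{PA}P - R_{1A}A,$$

where the $R_1$ are *effective* relaxation rates of the hyperpolarized
state (everything that destroys longitudinal order except conversion and
RF sampling). Each transient tips the magnetization by the flip angle
$\theta$: the observed amplitude is $\sin\theta \cdot M_z$ and the stored
magnetization is multiplied by $\cos\theta$. Because the pulse train is
periodic (period $T_R$), RF loss is equivalent to an extra first-order
decay $-\ln(\cos\theta)/T_R$, giving effective rates
$\tilde R_1 = R_1 - \ln(\cos\theta)/T_R$ and the closed form (pyruvate
shown; the products follow the usual rise-and-fall kernel)

$$P(t_n) = p_0 e^{-\tilde\rho_P t_n}, \qquad
  \tilde\rho_P = k_{PL} + k_{PA} + \tilde R_{1P}.$$

For an instantaneous bolus sampled just before each pulse this closed
form is *algebraically identical* to the discrete pulse-by-pulse
recursion, which is why `forward_model()` offers both routes and the test
suite holds them to $10^{-6}$ relative agreement (they actually agree to
machine precision; the brute-force ODE oracle with explicit RF events in
the test suite is the genuinely independent check).

### Assumptions

* unidirectional exchange (no lactate→pyruvate back-conversion);
* instantaneous bolus at `t0_s` (default 0): the pyruvate pool is fully
  present at the first transient. A delayed bolus is supported; transients
  before arrival are zero;
* spatially homogeneous signal in the selected slab — no perfusion or
  compartment modeling;
* constant flip angle and TR across the array.

## Fitting

`fit_kinetics()` uses a sequential two-stage scheme (a joint mode is
available):

1. **Pyruvate stage.** From the pyruvate maximum onward, fit
   $S_P(\tau) = S_0 e^{-\tilde\rho_P\tau}$. This measures the precursor's
   total effective decay *from the data*, so no assumption about
   pyruvate $T_1$ enters the product-channel rates.
2. **Product stage.** With $S_0$ and $\tilde\rho_P$ fixed, fit each
   product channel with
   $S_X(\tau) = k_{PX} S_0
   \frac{e^{-\tilde\rho_X\tau} - e^{-\tilde\rho_P\tau}}
        {\tilde\rho_P - \tilde\rho_X} + X_0 e^{-\tilde\rho_X\tau}$,
   where $X_0$ absorbs product signal already present at the fit start.
   The product decays $R_{1L}, R_{1A}$ are fixed to $1/30$ s⁻¹ by default
   (typical ¹³C $T_1 \approx 30$ s at 7 T) because freeing all decays on
   90-point channels is ill-conditioned; `free_decays = TRUE` frees them.

Numerical choices: bounded Levenberg–Marquardt (`minpack.lm::nls.lm`,
`ftol = ptol = 1e-12`, 200 iterations), bounds $k \in [0, 1]$ s⁻¹,
multi-start (3 starts, multiplicative perturbations 0.3× and 3×) against
local minima, rate initialization 0.01 s⁻¹, $\tilde\rho_P$ initialized
from a log-linear regression of the decaying pyruvate tail. Standard
errors come from the residual Jacobian at the optimum. Degenerate inputs
abort with diagnostics rather than returning silent nonsense: a pyruvate
maximum on the last transient (no decay to fit) and an all-zero pyruvate
channel are errors; all-zero product channels return $k = 0$ with zero
SE. Because amplitudes enter both stages on the same arbitrary scale,
rescaling all channels together leaves the rate constants unchanged,
while rescaling one product channel alone scales its rate constant
proportionally — units cancel only through the pyruvate amplitude. This
identifiability property is tested.

## Spectral processing

The per-transient chain mirrors standard dynamic ¹³C workflows:
exponential apodization (default 10 Hz, the lower end of the 10–12 Hz
range typical for such data), FFT with first-point halving (flat
baseline), automatic phasing, chemical-shift referencing against the
constant urea phantom line, trapezoidal window integration (default
±0.8 ppm windows around pyruvate 171.0, lactate 183.2, alanine 176.5,
urea 163.5 ppm — wide enough for 10–12 Hz broadened lines at 7 T,
disjoint for this shift table). Signed areas are retained for fitting;
ratio computation clips negatives at zero.

**Phasing.** Manual phasing is replaced by two reproducible criteria.
The zero-order phase minimizes the squared negative real intensity
(coarse 4° grid, then golden-section refinement); on spectra of in-phase
Lorentzians this criterion is empirically exact to well under a degree.
The optional first-order term is estimated from the arguments of the
spectrum at its peak maxima, read on a zero-fill-interpolated grid (an
off-grid line carries a spurious argument at its maximum *bin*;
interpolation puts the maximum on the line center, where the argument
equals the local phase error), then regressed on position with magnitude
weights and a single 20° outlier-trimming pass. The trim matters because
the dispersive tail of a strong neighbor can rotate the apparent phase
of a weak line by tens of degrees — which is also why `extract_series()`
phases each transient with the zero-order term only by default:
per-transient first-order estimation on sparse spectra is unstable, and
a first-order error is not part of the emulated acquisition. Both
decisions are switchable.

**Integration and its limits.** Window integration of Lorentzians is
never complete: a window of $\pm W$ around a line of half-width
$\gamma$ captures $(2/\pi)\arctan(W/\gamma)$ of its area (this closed
form is one of the micro-oracles in the test suite). Two consequences
are documented rather than hidden. First, absolute amplitude recovery to
better than 1% needs windows of $\gtrsim 60$ half-widths *and* well
separated lines; the round-trip test therefore uses a wide layout (20 ppm
spacing, 2 Hz lines, ±2.5 ppm windows, per-window linear baseline) and
checks transients above 5% of each channel's maximum — below that floor
the tail leakage of neighboring lines dominates relative error for any
window integrator. Second, because the captured fraction is common to
all channels under equal linewidths, the *ratios* and the *fitted rate
constants* are insensitive to it; the default pipeline (±0.8 ppm
windows, 10 Hz broadening) recovers rate constants within 5% end-to-end
even though single amplitudes are ~10% short.

## The synthetic cohort

`default_cohort_config()` encodes the emulated study: three groups of
ten subjects (healthy controls at 20 weeks; KC-model mice with early
lesions at 20 weeks; KC mice with advanced lesions at 30 weeks), with
group-mean rate constants and between-subject SDs set to the published
in vivo values for this model (control $k_{PA}$ 0.0098 ± 0.0005,
$k_{PL}$ 0.0125 ± 0.0005 s⁻¹; KC-20 0.0076 ± 0.0006 / 0.0224 ± 0.0004;
KC-30 0.0055 ± 0.0005 / 0.0296 ± 0.0004). Acquisition defaults follow
the in vivo protocol: 90 transients, TR 2 s (178 s time axis), 12°
pulses, 2048 complex points. Subject parameters are independent
Gaussians truncated at zero — the simplest generative model consistent
with mean ± SD reporting; a warning fires if half or more of a
parameter's mass would truncate.

Values the source data do not pin down were chosen once, as plausible
field values, and are exposed as configuration:

* **Dynamic noise**: circular complex Gaussian in the FID (or its
  amplitude-domain equivalent when FIDs are skipped), SD 0.01 of the
  first-transient pyruvate amplitude (nominal SNR 100); no in vivo SNR is
  stated for the emulated experiment. The Monte-Carlo calibration tests
  run at SNR 50.
* **p0 variability**: 5% between subjects (polarization and dose vary in
  practice; p0 cancels out of ratios and rate constants anyway).
* **Chemical shifts**: literature-standard values (see above; ¹H: TMSP
  0.00, lactate CH₃ doublet 1.33, alanine CH₃ doublet 1.48 ppm, J = 7 Hz).
* **Ex vivo concentrations**: group-mean Ala/Lac ratios ≈ 0.89 / 0.55 /
  0.29 with 10% subject SD — the published result gives the *direction*
  (falling with progression) but no concentration table, so magnitudes
  are plausible rather than anchored.
* **Pyruvate hydrate**: not simulated (never part of the ratios).

What passing tests show — and what they do not: the pipeline recovers
known ground truth under idealized conditions (Lorentzian lines, flat
baselines, instantaneous bolus, white noise). Real in vivo spectra add
baseline roll, B₀ drift, bolus dispersion, motion, and partial-volume
contamination from normal tissue; none of these are emulated, so green
tests validate the algorithms, not the biology.

## Ex vivo quantification

`quantify_ex_vivo()` integrates ±0.07 ppm windows around each methyl
doublet and the TMSP singlet and reports
$c_X = (I_X / I_{TMSP})(n_{TMSP}/n_X)$ with proton counts 9 (TMSP) and 3
(CH₃) — standard internal-standard practice, switchable off. A
denominator below the detection limit (default relative concentration
0.01, i.e. pure tail leakage) makes Ala/Lac `NA` with a diagnostic
rather than a huge ratio.

## Statistics

Group tables are mean ± SD; pairwise comparisons use the Welch
unequal-variance t-test (two-sided, $\alpha = 0.05$, no multiplicity
correction — matching the emulated study's analysis; two-sided is the
conservative default where sidedness is unstated). Zero variance in both
samples with equal means returns $p = 1$ by convention. The
implementation follows the Welch formula directly and is held to
`stats::t.test` at $10^{-8}$ in tests. `trend_check()` declares a group
ordering and requires strict monotonicity of group means; ties fail.

## Problem sizes and determinism

The test suite runs the full 90-transient acquisition everywhere it
matters, 100 random parameter draws for the ODE-oracle equivalence, 200
replicates for Monte-Carlo calibration at SNR 50, and 3×10-subject
cohorts for trend checks — sizes chosen to make sampling error small
relative to the tested tolerances while keeping a complete run around a
quarter of a minute. All randomness flows from explicit seeds; the same
configuration and seed reproduce a cohort bit-for-bit, including its
on-disk CSV/JSON form.

## Known limitations

* No bidirectional exchange, perfusion input function, or
  chemical-shift-imaging reconstruction; the model is the slab-style
  dynamic experiment.
* No vendor raw-data readers; the package defines its own plain-text
  containers.
* Ex vivo outputs are relative concentrations (no absolute mM
  calibration).
* First-order phase estimation degrades when weak peaks sit on strong
  neighbors' dispersive tails; it is off by default in the dynamic
  pipeline for exactly that reason.
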