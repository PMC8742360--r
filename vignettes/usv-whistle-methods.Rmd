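---
title: "Models and methods: intralaryngeal whistles and USV motor control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: intralaryngeal whistles and USV motor control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usvwhistle)
```

Rodent ultrasonic vocalizations (USVs) are not produced by vibrating vocal
folds but by an aerodynamic whistle: a glottal air jet whose instabilities
are entrained by acoustic feedback. This vignette describes the models this
package implements, the assumptions behind them, the defaults and where they
come from, and what the synthetic data can and cannot establish.

## The three candidate whistle mechanisms

Three intralaryngeal mechanisms have been proposed, distinguished by where
the jet (or shear layer) reattaches and by their frequency laws. With jet
exit speed $u$ (m/s), jet or cavity length $x$ (mm) and integer mode $n$:

* **Wall impingement**: the jet strikes the planar inner thyroid wall,
  $f_n = n\,u/x$.
* **Alar edge tone**: the jet strikes the alar cartilage edge,
  $f_n = n\,u/(2x)$.
* **Shallow cavity tone**: flow detaches over the ventral pouch and
  reattaches downstream, $f_n = u\,(n-\gamma)\,\kappa/x$ with empirical
  constants $\gamma = 0.25$ and $\kappa = 1/1.75$.

A *mode* indexes the possible stable whistle frequencies. It is not a
harmonic of an oscillator: modes can sound without the first mode present,
and for the cavity tone consecutive modes are evenly spaced by
$u\kappa/x$ but offset from harmonicity by $\gamma$.

Each law inverts exactly to a predicted length $x(u, f)$, which is how the
mechanisms are told apart: for the same observed $(u, f)$ the alar
prediction is exactly half the wall prediction and the cavity prediction is
$0.75/1.75$ of it, and only one of the three lands inside the space the
anatomy actually offers. `whistle_frequency()`, `predicted_length()` and
`predict_length_table()` implement the laws; `identify_mode()` resolves
which mode an observed dominant peak belongs to from the spacing to its
closest neighbouring mode, rounding $f_p/\Delta f$ to the nearest integer
with ties broken toward the lower mode (low modes dominate fictive USVs)
and flagging estimates whose ratio sits more than 0.25 from any integer.
The mode-spacing rule treats adjacent modes as separated by $f_1$; this is
exact for the jet tones and is applied to the cavity tone as well, whose
modes are evenly spaced but offset — the identification step is about
spacing, not absolute position, so the same rule serves all three.

## Detecting fictive USVs by spectral entropy

Excised-larynx recordings mix tonal whistles with flow-induced turbulence
noise. The detector exploits their difference in spectral concentration:

1. All channels are resampled to 240 kHz (polyphase antialiasing); the
   sound channel is band-passed 2.5–100 kHz with a 3rd-order Butterworth
   applied forward–backward (zero phase, effective order 6).
2. A power spectrogram is computed (Hamming window, `nfft = 2048`, overlap
   0 for detection; bins are stamped at window centres).
3. Per time bin, the power between 15 and 100 kHz is normalised to a
   distribution and its Shannon entropy is scaled by $\log_2(\mathrm{nfft}/2)$
   (= 11). Tonal bins score near 0, turbulence near 1.
4. Entropy is averaged into slices of 6 bins (rats) or 3 (mice); a fictive
   USV is a run of slices below threshold, at least two slices long, where
   a single above-threshold slice does not break the run. A trailing
   partial slice is dropped (slices are fixed bin groups).
5. The threshold is the mean minus two standard deviations of the entropy
   of whistle-free (unadducted) ramps during maximum flow — 0.7 for rats —
   or the signal-based 0.8 preset for mice.

The printed form of the entropy scaling constant is ambiguous between
$\log_2(\mathrm{nfft}/2)$ and $\log_2(\mathrm{nfft}^2/2)$; this package
uses the former, and the choice is self-consistent because the detection
threshold is derived under the same scaling. The alternative is available
via the `denominator` argument of `scaled_entropy()`. Time bins with zero
in-band power are assigned entropy 1 (maximally noise-like), so silence is
never detected as a call.

Peak-frequency contours are extracted by dynamic programming
(`extract_ridge()`): the path through the in-band spectrogram maximising
summed log power minus $0.05\,(\Delta\mathrm{bin})^2$ per step, with jumps
capped at 40 bins. The penalty was calibrated so that noiseless chirps at
the steepest slopes the detector meets are tracked within one bin; it is an
exposed argument, since no reference value exists for it. The ridge is
bin-quantised (117 Hz bins at the default settings); its endpoints can
wander one bin where the spectral mainlobe is flat, which washes out in the
per-slice averages used downstream.

## The embodied motor-control model

Two motor systems drive the whistle. The chain, implemented in
`forward_map()`:

* Respiratory muscles (RM) set subglottal pressure linearly:
  $p_t = \mathrm{RM} \cdot p_{max}$ with $p_{max} = 5$ kPa, capped at
  3 kPa in vivo.
* The thyroarytenoid (TA) closes the membranous glottis and, with the
  posterior cricoarytenoid / interarytenoid combination (PCA.IA), the
  cartilaginous glottis:
  $A_{gl} = (1-\mathrm{TA})A_{mmax} + (1-\mathrm{PCA.IA})A_{cmax}$.
  Lacking data on their interaction, PCA.IA is coupled to TA (a single
  adduction coordinate); a decoupled mode exists for sensitivity analysis.
* Flow follows a tube-with-obstruction (orifice plate) law with area-ratio
  correction,
  $V = C_d A_{gl}\sqrt{2 p_t/\rho}\,/\sqrt{1-(A_{gl}/A_{tr})^2}$,
  $\rho = 1.184$ kg/m³ at 25 °C. The reference for this step reports only
  qualitative agreement with a measured ramp, so the discharge coefficient
  $C_d$ is exposed (default 1) rather than asserted.
* Jet speed is $u = V/A_{gl}$. A consequence worth noting: the area
  cancels to first order, so glottal area barely affects jet speed (< 5%
  for halving/doubling around the measured area) — adduction gates the
  whistle rather than tuning it.
* The cricothyroid (CT) rotates the thyroid away from the glottis,
  lengthening the jet; TA weakly counteracts it:
  $x = x_{min} + (\mathrm{CT} - 0.24\,\mathrm{TA})(x_{max}-x_{min})$,
  floored at zero. The constant 0.24 calibrates $x$ to zero at full TA and
  zero CT. Because longer jets whistle lower, CT *lowers* USV frequency —
  opposite to its role in voiced phonation. A non-positive $x$ marks the
  whistle non-producible (sound gated off), not an error.
* The whistle sounds only where the Strouhal stability criterion
  $d/x \le St_n < 1$ holds, with $St_n = n f_1 d / u = n\,d/x$; the stable
  set is $\{n : n < x/d\}$, empty when the jet is as wide as it is long.
  The jet diameter $d$ is not defined by the source material; the
  equal-area circular diameter $d = 2\sqrt{A_{gl}/\pi}$ is used.

### Default rat geometry

The reference geometry is reconstructed from published summary
measurements, since the exact per-individual values are not tabulated:
anatomical wall/alar/cavity lengths 0.72/0.72/0.65 mm; $x_{min} = 0.35$ and
$x_{max} = 1.81$ mm (50% of the minimum and 150% of the maximum predicted
wall-jet length, which also makes the 0.24 calibration land on zero within
0.2%); $A_{cmax} = 0.075$ mm² chosen so that orifice flow at phonation
pressures 0.8–1.5 kPa lies in the observed 2.6–3.7 ml/s band;
$A_{mmax} = 0.4$ mm² so that full-abduction flow at resting pressures
matches quiet respiration (15–20 ml/s); tracheal area 0.95 mm² from the
1.1 mm cannula on which larynges are mounted. The in vivo caps (3 kPa,
10 ml/s) and the phonation threshold (0.8 kPa) are wet-lab reference
values; they parameterise defaults and are not reproduced computationally.

### Gesture inversion and identifiability

`invert_gesture()` recovers muscle gestures from a frequency trace plus a
pressure trace. RM is determined exactly ($p_t/p_{max}$). The laryngeal
pair (TA, CT) is found per sample by dense grid search (default 201×201)
over states whose first stable mode matches the target within 0.5 kHz,
choosing the feasible cell closest to the previous sample's solution.

Frequency and pressure alone do not identify TA: because jet speed barely
depends on area, the feasible set at each instant is a near-linear ridge
$\mathrm{CT} \approx 0.24\,\mathrm{TA} + c(f, p_t)$ — the model's motor
redundancy, which collapses only when flow is also known. Two design
choices make the inversion well-posed anyway:

* the first sample anchors the trajectory (minimal activation norm by
  default, or a supplied starting posture `init`), and
* the step metric weights TA moves four times more heavily than CT moves
  (`ta_step_weight`), attributing frequency tracking to CT. This encodes
  the model's own structure — TA mainly gates stability and barely moves
  $f_1$ — and prevents the solution from drifting along the redundancy
  ridge when targets move: with an isotropic metric a one-cell TA step and
  a one-cell CT step can tie, and tie-breaking then leaks frequency error
  into TA.

Samples with an empty feasible set are flagged and interpolated across
runs of at most 3; longer runs abort. Recovered trajectories are checked
against a smoothness bound (0.1 activation per 10 ms by default) and
violations are reported, not repaired — fast trill modulation (60 Hz)
genuinely requires CT strokes above that bound.

Because near-closed glottal states (tiny $A_{gl}$, hence tiny $d$ and
small $x$) are formally stable at very high $f_1$, the attainable
frequency set is broader than physiological; the minimal-step selection
keeps the inversion away from such states unless the target demands them.

`simulate_call()` replays a gesture through the forward map, reporting the
stable mode stack $\{n f_1\}$ per sample and synthesising the lowest
stable mode as a phase-continuous unit tone, silent where unstable.
`geometry_perturbation()` replays a fixed gesture with $x_{min}, x_{max}$
scaled jointly: at a fixed stable state $f$ scales exactly as $1/s$, which
is how a 20% (180 µm) length change shifts calls by over 10 kHz.

## Synthetic data: what it emulates and what it does not

`generate_ramp()` emulates the excised-larynx paradigm: a piecewise-linear
pressure ramp (presets 0.5 and 1.66 kPa/s, peak 1.5 kPa), orifice-law flow
through the adducted (cartilaginous-only) glottis, a wall-impingement
whistle — phase rate $2\pi n u(t)/x$ — active above the 0.8 kPa phonation
threshold while stable, and Gaussian noise with standard deviation
proportional to instantaneous flow (white up to 100 kHz, as turbulence
noise is), low-passed at 100 kHz. On/offsets carry a one-spectrogram-bin
raised-cosine fade to avoid clicks. Output is a deterministic function of
the seed.

The generator reproduces the *structure* the detector relies on — tonal
concentration against flow-scaled broadband noise, pressure-flow-frequency
covariation — but not realistic turbulence spectra, room acoustics,
microphone directivity, amplitude dynamics, or inter-individual anatomical
variation. Passing the detector tests therefore shows correct behaviour of
the detection logic under the stated noise model, not performance on real
recordings.

`generate_multimode_clip()` produces stationary multi-mode tones for
exercising mode identification; `generate_call_targets()` produces
feasible frequency + pressure targets for the common call types (flat
22 kHz at 0.65 kPa; 50 kHz with discrete steps; 50 kHz trill, ±5 kHz at
60 Hz, both at 1.8 kPa), verifying feasibility under the default geometry
at generation time.

## Numerical choices and problem sizes

* Units at interfaces: mm, mm², ml/s, kPa, kHz (m/s for jet speed);
  internal computation in SI. `u` [m/s] / `x` [mm] reads directly in kHz.
* Mode rounding breaks ties toward the lower mode; ratios more than 0.25
  from an integer are flagged low-confidence rather than rejected.
* The inversion grid (201×201), tolerance (0.5 kHz), interpolation limit
  (3 samples) and TA step weight (4) are arguments with those defaults.
* The test suite and analysis scripts use single ramps of 1.8 s at
  240 kHz, gestures of 0.2–0.5 s at 1 ms resolution, and $10^4$ random
  motor states for the algebraic identities — sizes at which every
  property they check is already stable.
* Statistical comparisons from published group summaries use the pooled
  (equal-variance) two-sample t test: pooling reproduces the reported
  p values from rounded summaries, a Welch variant is available behind a
  flag. P values recomputed from rounded means can differ from values
  computed on raw data in the last printed digit; such comparisons are
  reported but not asserted.

## Known limitations

* The model is steady-state: no muscle activation dynamics, no acoustic
  radiation or vocal-tract filtering, no amplitude model, and no fluid
  dynamics beyond the orifice law and the Strouhal criterion.
* TA is unobservable from frequency and pressure alone (see above); the
  recovered TA trace is the smoothest consistent one, not a measurement.
* Which of several stable modes actually sounds depends on local flow
  conditions the model does not resolve; synthesis defaults to the lowest
  stable mode and reports gate transitions as discrete events.
* The detector's thresholds are species presets derived for the reference
  recording chain; other microphones or noise floors may need re-derivation
  via `derive_threshold()`.
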