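---
title: "Methods: fNIRS risk detection and physiologically guided driving control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fNIRS risk detection and physiologically guided driving control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, the numerical choices, and the design
decisions behind `fnirsdrive`, in the spirit of a methods section. It states
no empirical result that the package's tests do not themselves compute.

## The problem

A passenger in a highly automated vehicle perceives developing risk seconds
before a collision becomes imminent. Functional near-infrared spectroscopy
(fNIRS) measures the cortical hemodynamic correlates of that perception:
oxygenated hemoglobin (ΔHbO) rises and deoxygenated hemoglobin (ΔHbR) falls
over the prefrontal cortex a few seconds after the evoking event. The package
implements a complete online loop: decode the passenger's subjective risk
from 8-channel fNIRS concentration changes, and use the resulting boolean
gate to make a reinforcement-learning driving agent safer — both immediately
(switching control to a conservative car-following law while risk is
flagged) and permanently (the agent clones the demonstrated safe action).

## Synthetic episodes

No recorded data ships with the package; the generator in
`generate_episode()` produces episodes with known ground truth so that every
downstream stage is testable.

* **Response model.** The risk boxcar is convolved with a canonical
  double-gamma hemodynamic response function (`hrf_double_gamma()`, peak ≈ 6 s,
  undershoot ≈ 16 s, peak-normalised). ΔHbR is −1/3 of ΔHbO lagged by 1 s —
  the standard magnitude ratio and lag used in fNIRS modelling. The per-channel
  response gain varies uniformly in [0.6, 1] to mimic spatial
  variation across the montage. The generator is a stand-in consistent with
  textbook hemodynamics, not a claim about any particular recording.
* **Noise model** (`noise_profile()`): sinusoidal cardiac (1.1 Hz, 0.05 µM),
  respiratory (0.25 Hz, 0.03 µM) and Mayer-wave (0.1 Hz, 0.04 µM) components
  with random phases, a linear drift (0.002 µM/s) and white sensor noise
  (0.02 µM), against a response amplitude of 0.3 µM. The components are
  placed below, inside and above the 0.01–0.90 Hz band so the band-pass is
  genuinely exercised. These amplitudes are realistic for prefrontal
  continuous-wave fNIRS, where physiological oscillations are commensurate
  with task responses.
* **Timing.** Sample intervals jitter ±10 % around 50 Hz, so cubic-spline
  resampling does real work. The button trace equals risk membership shifted
  by a 0.8 s reaction delay — a plausible motor latency.
* **Protocol shape** (`scenario_profile()`): 20 s of resting baseline, 10 s
  of stable driving, then one randomised risk event of 3–6 s, in a 40 s
  episode. Thirty episodes per scenario is the recorded-protocol scale.

What the generator does **not** model: motion artifacts, optode-coupling
changes, superficial (scalp) hemodynamics, and inter-subject variability in
HRF shape. Passing tests therefore demonstrate correctness of the pipeline
and recoverability of a textbook response, not field performance on real
recordings.

## Preprocessing

Each chromophore is processed separately: per-channel subtraction of the
20 s resting mean, cubic-spline resampling to exactly 50 Hz, then the
real-time filter. The filter is the difference of two double exponential
moving averages (DEMA), a MACD-style band-pass:

$$y_1[n] = (1-\lambda)y_1[n-1] + \lambda x[n],\quad
  y_2[n] = (1-\lambda)y_2[n-1] + \lambda y_1[n],\quad
  \mathrm{DEMA}_\lambda[n] = 2y_1[n]-y_2[n]$$

with output $\mathrm{DEMA}_{\lambda_1} - \mathrm{DEMA}_{\lambda_2}$,
$\lambda_1 = 0.001$, $\lambda_2 = 0.055$, followed by a causal 100-point
simple moving average. DEMA's appeal for online use is its reduced lag
relative to a single EMA at equal $\lambda$ (a property the test suite
checks on a ramp input).

**Passband characterisation.** The closed-form magnitude response is in
`freq_response()`. Measured −3 dB relative to the passband maximum, the
DEMA-difference band-pass stage spans 0.0159–0.9032 Hz at 50 Hz sampling —
the conventional fNIRS band (its nominal statement, 0.01–0.90 Hz, rounds
the lower edge down to one significant figure). The 100-point smoother that
follows is deliberately excluded from this characterisation: a 2 s moving
average is −3 dB at ≈ 0.22 Hz, so including it would describe the smoother,
not the band-pass. `band_edges(include_sma = TRUE)` and
`freq_response_table()` expose the full-cascade response for audit.

**State handling.** Filter recursions are seeded with the first sample
(`init = "first"`), avoiding the multi-second start-up transient of
zero-initialisation; zero-init remains available. Batch and streaming paths
(`macd_bandpass()` / `macd_step()`) implement the same arithmetic and agree
to better than 1e−10.

**Buffering.** The filtered stream is windowed into 5 s, 8 × 250 buffers
every 0.2 s (the online cadence; the buffer keeps 1 s of warm-up so the
newest 4 s are clean). The activity indicator ΔCOE = (ΔHbR − ΔHbO)/2 is
computed after filtering, and only ΔCOE feeds feature extraction. Window
labels are the button state at the newest sample.

## Features and selection

Each channel's newest 200 samples are decomposed with the 8-tap Daubechies-4
wavelet to 4 levels (symmetric boundary extension; coefficient-set lengths
103/55/31/19/19 for n = 200), giving 5 coefficient sets. Twelve summary
features per set — Shannon entropy, the 5/25/75/95 percentiles and median,
mean, SD, variance, RMS, zero- and mean-crossing counts — yield 60 features
per channel, 480 per window. Per channel, the 4 features with the highest
information gain against the window labels are kept: 32 features total.

Numerical choices that were genuinely open:

* **Boundary mode.** Symmetric extension (the common choice for short
  biomedical windows); a periodised mode is provided because it makes the
  transform exactly orthogonal, which the Parseval test uses. The mode is
  part of the feature registry since coefficient lengths depend on it.
* **Entropy probability.** The entropy of a coefficient set uses the
  energy distribution $p_i = c_i^2 / \sum_j c_j^2$ (natural log). This is a
  documented choice, not asserted as canonical.
* **Information-gain discretisation.** Continuous features are binned into
  10 quantile bins (in bits); a best-single-threshold variant is available.
  Ties in selection break deterministically toward the lowest feature
  index, so degenerate (constant) channels still return 4 features and are
  flagged.
* **Scope.** Selectors are fitted independently per subject and per
  scenario; no cross-subject transfer is attempted.

## The detector

Six base classifiers — AdaBoosted decision tree, Gaussian naive Bayes,
RBF-SVM and logistic regression, plus a random forest and an MLP — vote
softly: the risky probability is the unweighted mean of the members'
probabilities, thresholded at 0.5 (ties resolve to risky). Boosting is
SAMME with 50 rounds; depth-2 trees; members without native case weights
(GNB, SVM) are fitted on weighted resamples; the SVM and MLP see
standardised features. None of these hyperparameters is critical to the
package's claims and all live in `ensemble_spec()`.

Evaluation uses balanced accuracy (BA), the mean of sensitivity and
specificity, under stratified 5-fold cross-validation; class imbalance is
handled only through the metric, not by resampling. Above-chance detection
is certified by a label-permutation test of the pooled out-of-fold
predictions.

One structural limit is worth stating: labels are button presses, delayed
by reaction time, while features carry the hemodynamic response, delayed
and smeared by several seconds. Windows near risk onsets and offsets are
therefore intrinsically ambiguous even without noise, which caps noiseless
cross-validated BA below 1 (the acceptance suite asserts > 0.9 noiseless
and > 0.5 with significance at default noise).

## Simulator

A longitudinal kinematic environment (`scenario_config()`, `sim_step()`)
implements the three study scenarios — emergency braking (both vehicles
50 km/h, 50 m apart, hard braking triggered at a uniform 20–40 m relative
distance), cut-in (50 vs 40 km/h, 80 m, instantaneous merge at a random
time after 10 s), and pedestrian crossing (40 km/h, crossing 300 m ahead at
a random time after 10 s, 1.5 m near-miss threshold). The agent sees the
8-dimensional state (ego and front-agent positions and velocities in x, y)
and outputs a normalised acceleration in [−1, 1].

Choices the study description leaves open, fixed here and recorded:

* Action map [−1, 1] → [−8, +3] m/s² (emergency braking to brisk
  acceleration); forward-Euler kinematics at dt = 0.05 s (0.1 s in the
  reduced configuration); 40 s episode cap.
* The first 10 s of each episode are scripted cruise (the stable-driving
  span experienced by the participant); the agent takes over at handover.
* Termination: collision (gap below the 5 m vehicle length), pedestrian
  clearance < 1.5 m, ego standstill after handover, or the time cap.
* Reward (entirely a design stand-in, as none is prescribed):
  $+w_v(1-|v-v_\mathrm{ref}|/v_\mathrm{ref})
  - w_c\,\mathbb{1}[\text{crash/near-miss}] - w_j\min(\mathrm{jerk}^2,400)
  - w_r\min(E_v,1)$ with $w_v{=}0.1$, $w_c{=}10$, $w_j{=}0.01$, $w_r{=}1$.
  The jerk term is capped so no single step can outweigh the crash penalty;
  the risk-field term supplies dense shaping. Halving or doubling any
  weight preserves the qualitative ordering (crash ≪ everything else).
* IDM fallback: $\dot v = a_{\max}(1-(v/v_0)^4-(x^*/\Delta x)^2)$,
  $x^* = x_0 + \max(0, vT + v\Delta v/2\sqrt{a_{\max}b_{\max}})$, with
  $v_0$ = scenario speed, $x_0$ = 2 m, $T$ = 1.5 s, $a_{\max}$ = 2,
  $b_{\max}$ = 4 m/s², exponent 4; output clamped to
  $[-b_{\max}, a_{\max}]$. Driven alone it completes all scenarios without
  collision (a tested invariant), which is what qualifies it as the safe
  fallback.

## Guided TD3

The agent is standard TD3 — twin critics with clipped double-Q targets and
target-policy smoothing, delayed policy updates, Polyak-averaged targets —
with two modifications:

1. **Risk-gated switching**: the executed action is
   $a = (1-k)\,a_{RL} + k\,a_{IDM}$ with boolean $k$ from the detector (or
   the ground-truth risk phase in oracle mode).
2. **Behaviour cloning in the actor update**: the actor ascends
   $Q_1(s,\pi(s))$ while descending $k\,\lVert a_{IDM}-\pi(s)\rVert^2$,
   so only gated transitions contribute cloning gradient. The cloning
   weight defaults to 1 (no trade-off coefficient is prescribed; the knob
   is exposed). With $k = 0$ everywhere the update is exactly the plain
   TD3 actor step — a tested identity.

The published critic target omits smoothing noise; standard TD3 smoothing
is included by default and can be disabled (`target_noise = 0`). During
gated steps the replay stores the executed IDM action by default
(`store_executed`), so critics learn on executed behaviour while the
cloning term uses the stored $a_{IDM}$; storing the raw proposal instead is
a flag, since either reading of the protocol is defensible.

Networks are 2 × 256 ReLU layers (tanh actor head) by default, trained by
explicit backpropagation with Adam — the networks are small enough that a
dependency-free implementation is the simplest correct tool here.
Warm-up exploration samples accelerations uniformly from [−2, 2] m/s²
(comfortable driving magnitudes) rather than the full action range: an
asymmetric braking-heavy action space otherwise makes random exploration
stall the vehicle before any risk event can develop, which would empty the
comparison of content. The policy itself is never restricted.

**Protocol.** Episodes alternate: odd episodes are guided training episodes
(gate live, exploration on, learning on); even episodes are agent-only
tests (gate forced 0, deterministic policy, no learning). The A/B
comparison trains a control agent with the gate disabled on identical
episode seeds.

## Metrics and statistics

* **Driving risk field**: $|E_v| = G R_2 M / |r|^{k_1} \cdot
  e^{k_2 |v_2| \cos\theta_2}$ with $G=0.001$, $R_2=1$, $M=1705$ kg,
  $k_1=1$, $k_2=0.05$. The field is evaluated front-on-ego: $r$ points
  from the front agent to the ego vehicle and $v_2$ is the front agent's
  velocity (the other orientation is available by passing the arguments
  accordingly; magnitudes differ only through $\cos\theta_2$).
* **TTC** = (gap − vehicle length)/closing speed while closing; +∞ when
  the gap is opening or constant (excluded from minima unless nothing
  closes); 0 at contact. **Jerk** by central differences (one-sided at the
  endpoints), positive and negative samples averaged separately.
* **Statistics**: Friedman omnibus on subjects × models BA (via
  `stats::friedman.test`), Nemenyi all-pairs post hoc from the studentised
  range on mean-rank differences; one-sided Wilcoxon tests after robust
  z-score outlier removal ($z = (x-\mathrm{med})/1.4826\,\mathrm{MAD}$,
  threshold 3, removal counts logged). An all-constant BA matrix returns
  statistic 0 / p 1 by convention rather than an undefined rank test.

## Problem sizes used by the tests

The suite runs the study conditions at desk scale: 4–8 synthetic episodes
per detector fixture at a 0.5 s slice stride; the guided-versus-control
comparison uses 5 seeds × 10 episode pairs on scenario 1 with 32-unit
hidden layers, a 64-sample batch, 200-step warm-up and dt = 0.1 s
(`quick_config()`). These sizes were chosen so the full suite completes in
a few minutes while leaving every qualitative contrast intact; the default
configuration (30 pairs, 256-unit layers, dt = 0.05 s) is the
protocol-scale setting.

## Known limitations

* The generator's HRF is canonical; no per-subject shape variability.
* The cut-in scenario has no lateral dynamics (instantaneous merge).
* The reward and all unpublished constants are documented stand-ins; the
  learning-curve comparisons test ordering (guided ≥ control), not
  absolute returns.
* Label latency bounds detector ceiling performance, as discussed above.
* Single-lane, single-front-agent traffic only.
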