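---
title: "Multi-timescale normalized value coding: model and analysis methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-timescale normalized value coding: model and analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normadapt)
```

## The model

`normadapt` simulates value coding in a two-stage, cascaded
divisive-normalization circuit. Each of the `N` choice options is
represented by one excitatory (rate-coding, `R`) and one inhibitory
(gain-control, `G`) unit in each of two subcircuits, a *fast* circuit
capturing within-trial dynamics and a *slow* circuit integrating reward
information across trials. Writing `V_i(t)` for the value input of
option `i`, the fast circuit obeys

    tau_F dG_i^F/dt = -G_i^F + sum_j omega_ij R_j^F + sum_k alpha_ik R_k^S
    tau_F dR_i^F/dt = -R_i^F + V_i / (1 + G_i^F)

and the slow circuit

    tau_S dG_i^S/dt = -G_i^S + sum_j beta_ij R_j^S
    tau_S dR_i^S/dt = -R_i^S + V_i / (1 + G_i^S)

Divisive normalization enters through the `V / (1 + G)` nonlinearity:
each output unit's drive is divisively scaled by its paired gain unit,
which pools network excitatory activity. The slow circuit's excitatory
output feeds the fast gain units (`alpha`), so the recent value history
modulates the gain with which current options are encoded — the
mechanism by which temporal context shapes value coding and, through
it, choice.

Model assumptions, all exposed as `norm_params()` fields:

* **All-ones weights** (`omega = alpha = beta = 1`) by default:
  inhibition is a single pool within each stage and no
  excitation/inhibition asymmetry is assumed. With uniform weights the
  gain units of a stage receive identical input and behave as one pool.
* **Equal excitatory and inhibitory time constants** within a stage;
  only two timescales exist, `tau_F` and `tau_S`.
* **Only the ratio `tau_S / tau_F` matters**: rescaling both time
  constants and time itself leaves trajectories invariant (verified as
  a property test). We default `tau_F` to 100 ms, the empirically
  motivated timescale of fast normalization dynamics in decision
  circuits, and express sweeps in terms of the ratio.
* **Zero baseline**: the all-zero state is the fixed point under zero
  input, and sessions start from it.

## Numerical integration

`simulate_network()` integrates the `4N` equations with the classical
fixed-step RK4 scheme (compiled code; a plain-R engine is retained and
tested to produce bit-identical trajectories). The default step is
1 ms, matching the millisecond-level evaluation of the behavioral
analyses; sessions of ~1,600 s integrate in well under a second.

Two numerical details matter:

* **Grid alignment.** Value inputs are piecewise constant with
  discontinuities at trial on/offsets. The integrator requires `dt` to
  divide every segment boundary, so no RK4 step straddles a
  discontinuity, and all four stage evaluations use the value at the
  step start. Sampling the next segment for the last stage would
  silently degrade the scheme to first order at every boundary; with
  alignment the empirical convergence order on the block-stepped
  scenario is ~3.9.
* **State continuity.** The state is never reset: it carries across
  trials, across the two blocks of a session, and through inter-trial
  intervals (where `V = 0`), because the slow circuit's memory *is* the
  phenomenon under study.

`steady_state()` solves the fixed point for constant input by damped
fixed-point iteration, slow stage first (it is autonomous), then the
fast stage given the equilibrium slow drive; a long forward integration
is the fallback if iteration stalls, and the returned state carries its
residual. For one option and all-ones weights the fixed points are
roots of quadratics (`R(1 + R) = V` for the slow stage), which the test
suite uses as exact oracles.

## The task and the synthetic-session generator

The behavioral paradigm is a delayed two-alternative forced choice
between juice rewards whose magnitudes appear as stacks of squares.
Sessions contain two contiguous blocks distinguished only by the
*spread* of their background rewards: each block mixes ~60% adapter
trials (two draws from the block's magnitude distribution) with ~40%
test trials (a fixed reference against one of five variable
magnitudes). Test trials are identical in both blocks; adapter
distributions share a mean but have narrow versus wide standard
deviation. Efficient coding predicts sharper choice curves in the
narrow block.

`generator_config()` states this world explicitly; its defaults are the
paradigm's canonical statistics and conventional laboratory values:

| parameter | default | basis |
|---|---|---|
| trials per block | 289 | typical completed block length in this paradigm |
| adapter fraction | 0.60 | canonical trial composition |
| test magnitudes | 3, 4, 5, 6, 7 vs reference 5 | five variable rewards straddling a mid-grid reference (grid 1–9 squares) |
| adapter mean | 5 | equal to the test-range center, shared by both blocks |
| adapter SD (narrow / wide) | 1 / 3 | spread contrast on the 1–9 grid; wide is near-uniform after truncation |
| ITI | uniform 600–900 ms (integer ms) | canonical jitter range |
| abort rate | 0.15 | matches ~85% completed trials |
| time-out after abort | 3,000 ms | typical post-error time-out |
| display duration | 2,100 ms | 1,200 ms fixation hold + 500 ms saccade window + 400 ms target hold |

Adapter magnitudes are drawn from a discretized truncated Gaussian on
the magnitude grid; only the mean/SD structure is prescribed, the
distribution family is a package choice.
Aborted trials keep their displayed options (they drive the model's
input) but carry no choice, and their time-out lengthens the following
interval. Integer-millisecond times keep session files lossless in
plain text and keep every event on the 1 ms integration grid.

`synthetic_chooser()` is a stand-in decision maker — a base-10 logistic
in the magnitude difference with known sensitivity and bias — so the
model-versus-behavior pipeline is testable end to end without animal
data, and so psychometric recovery can be scored against ground truth.

## From sessions to model input

`compile_value_timeline()` gates each trial's value vector on during
`[display_on, display_on + display_duration)` and sets it to zero
between trials, the convention of the model's demonstration scenario.
The mapping from reward magnitude to model value input is the identity
by default: the paradigm offers no calibration of subjective value, and
juice-type differences can be absorbed into the reference magnitude.
`value_map` is exposed for anything more elaborate.

## Choice readout

`predict_choices()` integrates a session once and averages each
option's fast excitatory rate over a readout window, by default the
final 200 ms of the display (the plateau after the onset transient;
the window is configurable and results in this package are reported at
the default).

Two channels are derived:

* **Argmax** — the option with the larger windowed rate, ties (within
  `tie_epsilon`, measure-zero under the continuous dynamics) broken
  toward option a. This channel is deterministic, and with uniform
  weights it is *degenerate as a stochasticity measure*: the shared
  gain pool guarantees that the plateau rate difference has the sign of
  the value difference, so argmax choice curves are step functions in
  every context. The package exports it because it is the natural
  per-trial decision rule, but block contrasts built on it are
  identically zero (we verified this across timescale ratios and even
  extreme adapter-variance contrasts).
* **Probabilistic** — choice stochasticity expressed the way the
  circuit actually carries it: in the trial-to-trial *reliability* of
  the rate difference. If the network consistently produces a large
  difference for the same option pair, choice is reliable; if the
  difference fluctuates across trials, choice is stochastic. The
  probability of choosing option b is a base-10 logistic in the rate
  difference divided by a block-specific noise scale,
  `p = 1 / (1 + 10^(-(r_b - r_a) / (gamma * sigma_block)))`.

`sigma_block` is estimated from the model's own activity: every
displayed trial yields a normalized-gain sample
`g_t = (r_a + r_b) / (v_a + v_b)` (at plateau this equals
`1 / (1 + G)`); within a block, per-level means are removed and the
standard deviation of *successive differences* (divided by `sqrt(2)`)
estimates the per-trial diffusion of the value-coding state. The
increment estimator is used instead of the raw SD because it is
insensitive to slow deterministic drift and has far lower estimation
variance on autocorrelated series; it is the component of the
variability that the block's reward statistics actually drive. Wide
blocks, whose adapter values jump more from trial to trial, diffuse the
slow state faster, inflate `sigma_block`, and flatten the choice curve
— the efficient-coding direction, as a first-order effect.

Two auxiliary parameters:

* `noise_gamma` (default 100) converts the diffusion scale into the
  assumed readout noise. The model's deterministic rate differences are
  far larger than its trial-to-trial diffusion, so an unscaled
  signal-to-noise readout saturates; `gamma` was fixed once so that
  model choice-curve slopes land in the same range as typical
  behavioral slopes (~1–2 per magnitude unit). Block contrasts divide
  out the scale: the narrow-minus-wide direction is unchanged across
  `gamma` within the unsaturated regime.
* `burn_in` (default `3 * tau_slow`, capped at half the first block)
  excludes the session-start relaxation from the probabilistic channel.
  The network starts at the zero baseline and the slow circuit takes
  ~3 time constants to reach its operating point; that ramp is a
  property of the arbitrary initial condition, not of the block's
  reward statistics, and it otherwise dominates the variability of
  whichever block happens to come first.

## Psychometrics

`fit_choice_curve()` fits the standard sigmoid
`y = 1 / (1 + 10^((x50 - x) s))` to the probability of choosing the
variable option as a function of its magnitude. The default objective
is least squares on the per-level choice proportions (fit quality is
reported as an RMSE over the same levels); a Bernoulli-likelihood
objective is available. Initialization takes `x50` from the level whose
proportion is nearest 0.5 and the slope from a base-10 logit line; the
slope is bounded to `[0, s_max]` with `s_max = 10` per magnitude unit
(a curve that rises from 0.1 to 0.9 within ~0.2 units — effectively a
step on the unit-spaced grid). Fits with all responses on one side or
with the slope pinned at the bound are flagged `boundary` rather than
silently returned. Noiseless proportions are inverted to ~1e-7.

The adaptation-effect measure for one session is the normalized slope
difference `(s_narrow - s_wide) / (s_narrow + s_wide)`; the symmetric
form is adopted because it is scale-free (in particular,
independent of `noise_gamma`); the raw difference is also returned.

## Adaptation statistics

* `mean_effect_tests()` — one-sample two-tailed t test of the
  per-session slope differences against zero plus a sign-flip
  permutation test (sign flipping under the null of no block effect is
  the natural exchangeable scheme for paired block contrasts). For `n <= 20` sessions all `2^n`
  sign patterns are enumerated (exact p); otherwise Monte Carlo with
  the add-one correction `(b + 1) / (n_perm + 1)`.
* `correlate_model_behavior()` — Pearson correlation with two-tailed p
  between model and behavioral per-session effects;
  `sign_agreement()` adds the chi-squared comparison of effect
  directions.
* `tau_sweep()` — re-runs the model at a grid of timescale ratios and
  reports `r(ratio)`. The default grid (50–1250, i.e. `tau_S` of
  5–125 s at `tau_F = 100` ms) spans the range from roughly one trial
  of memory to many dozens of trials; broader grids (e.g. ratios up to
  2500, `tau_S` = 250 s) are supported by passing `ratios` directly.
* `magnitude_shuffle()` / `iti_shuffle()` — the permutation controls:
  the first permutes trial *content* across temporal slots (slots keep
  onset, duration, following ITI, and block label), destroying the
  reward sequence while preserving timing; the second permutes the
  ITIs (time-outs included) while preserving content order,
  recomputing onsets cumulatively. Both accept an explicit permutation
  so the identity is testably a no-op.
* `shuffle_null()` — re-runs the model on `n_reps` shuffled copies of
  every session and reports the two-sided empirical p of the observed
  model-behavior correlation against the null distribution, with the
  add-one correction.

All stochastic procedures take explicit seeds; child seeds are derived
deterministically from a root seed, and `run_pipeline()` stamps outputs
with a configuration hash.

## What the synthetic world does and does not establish

The generator reproduces the paradigm's *statistical* structure: block
composition, the narrow/wide spread contrast with a common mean, ITI
jitter, aborts with time-outs. It does not emulate satiety or
motivation drifts, juice-type preference differences, session-to-session
parameter drift, or reaction times, and the stand-in chooser is
stationary by design. A green adaptation-direction test therefore
establishes that *the model, fed sequences with the stated statistics,
adapts in the efficient-coding direction* — not that any particular
animal did; no empirical dataset ships with the package, and the
headline statistics of any specific experiment (particular t, r and p
values) are not reproducible from synthetic data. The model-behavior correlation
machinery is validated by self-recovery (behavior generated by the
model at a known timescale ratio is matched best near that ratio) and
by calibration of the shuffle nulls, which are claims about the
pipeline, not about animals.

## Known limitations

* The diffusion-based noise estimator assumes a discrete magnitude
  grid (per-level means need repeated levels); continuous `value_map`
  outputs would need binning.
* At very large timescale ratios the burn-in cap (half the first
  block) leaves some session-start ramp in the first block's
  statistics.
* The probabilistic readout's overall noise scale (`noise_gamma`) is a
  bridging parameter fixed by calibration to behavioral slope ranges,
  not derived from the circuit; only contrasts and correlations, which
  are invariant to it, should be interpreted.
* With uniform weights the slow circuit tracks the *sum* of option
  values; non-uniform `alpha` (option-matched slow input) is supported
  but untested against any empirical target.
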