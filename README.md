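# normadapt

Simulation and analysis of **multi-timescale divisive normalization** in
value-based decision-making. The package is for computational
neuroscientists and decision scientists who want to ask how the
*statistics of recent rewards* — not just the current options — shape
choice behavior through the dynamics of a value-coding circuit.

## The model

Each choice option is represented by an excitatory/inhibitory unit pair
in two cascaded subcircuits. The fast circuit (time constant `tau_F`,
~100 ms) carries within-trial value coding; the slow circuit (`tau_S`,
tens of seconds) integrates value inputs across trials and feeds the
fast circuit's gain-control units:

    tau_F dG_i^F/dt = -G_i^F + Σ_j ω_ij R_j^F + Σ_k α_ik R_k^S
    tau_F dR_i^F/dt = -R_i^F + V_i / (1 + G_i^F)
    tau_S dG_i^S/dt = -G_i^S + Σ_j β_ij R_j^S
    tau_S dR_i^S/dt = -R_i^S + V_i / (1 + G_i^S)

Divisive normalization (`V / (1 + G)`) makes value coding relative to
both the *spatial* context (the other option, via the shared gain pool)
and the *temporal* context (recent rewards, via the slow circuit). Only
the ratio `tau_S / tau_F` affects behavior.

Around the circuit sits the full behavioral-adaptation pipeline:

* **Synthetic sessions** (`generate_session()`): two-alternative choice
  sessions with two blocks of trials whose background ("adapter")
  reward distributions share a mean but differ in spread (narrow vs
  wide), interleaved with fixed test trials — reference magnitude 5
  against variable magnitudes 3–7; ~289 trials/block, 60% adapters,
  ITIs jittered 600–900 ms, 15% aborts with time-outs.
* **Simulation** (`simulate_network()`, Rcpp RK4 at 1 ms) over the
  session's gated value timeline, state carried continuously.
* **Choice readout** (`predict_choices()`): windowed fast-circuit
  rates per trial, argmax choices, and graded choice probabilities in
  which each block's choice stochasticity reflects the trial-to-trial
  variability of the model's rate differences.
* **Psychometrics** (`fit_choice_curve()`): the standard sigmoid
  `y = 1/(1 + 10^((x50 − x)·s))`; the slope `s` measures choice
  sensitivity, and the per-session adaptation effect is the normalized
  slope difference `(s_narrow − s_wide)/(s_narrow + s_wide)`.
* **Statistics** (`mean_effect_tests()`, `correlate_model_behavior()`,
  `tau_sweep()`, `shuffle_null()`): t and sign-flip permutation tests
  of the mean effect, model–behavior correlation across sessions,
  timescale-ratio sweeps, and magnitude/ITI shuffle nulls.

Efficient coding predicts — and the model reproduces — *steeper choice
curves in narrow-variance blocks*.

## Worked example

```r
library(normadapt)

# one synthetic session with the default task statistics
session <- generate_session(generator_config(), seed = 12)
session <- synthetic_chooser(session, sensitivity = 1, seed = 34)

# run the cascaded network (tau_F = 100 ms, tau_S = 60 s) over the session
preds <- predict_choices(session, norm_params(tau_ratio = 600))
attr(preds, "noise_scales")
#> # A tibble: 2 × 3
#>   block    sigma n_noise
#>   <chr>    <dbl>   <int>
#> 1 wide   0.00126     234
#> 2 narrow 0.00109     289

# block-wise model choice curves and the adaptation contrast
model_slope_difference(preds)
#> # A tibble: 1 × 9
#>   s_narrow s_wide slope_diff norm_slope_diff x50_narrow x50_wide ...
#> 1     1.80   1.58      0.228          0.0674       5.00     5.00

# the synthetic subject, for comparison
behavior_slope_difference(session)
#> # A tibble: 1 × 9
#>   s_narrow s_wide slope_diff norm_slope_diff x50_narrow x50_wide ...
#> 1     1.26   1.14      0.121          0.0503       4.85     4.79
```

Reading the numbers: the wide block's value-coding state fluctuates
more from trial to trial (`sigma` 0.00126 vs 0.00109), so the model's
wide-block choice curve is flatter (`s_wide` 1.58 vs `s_narrow` 1.80) —
a positive normalized slope difference (+0.067), i.e. sharper choices
after a narrow reward context. Both curves stay centered at the
reference magnitude (`x50 ≈ 5`): the context changes choice
*sensitivity*, not juice preference. Across many sessions the model's
mean contrast is reliably positive (see `tests/testthat/test-acceptance.R`).

`run_pipeline(run_config(...))` chains all stages (generation, chooser,
simulation, fits, contrasts, optional sweep and shuffle tests) and
writes CSV/JSON outputs stamped with a config hash and seed. A thin
command-line wrapper with `generate | analyze | sweep | shuffle-test`
subcommands lives at `inst/cli/normadapt-cli.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end analysis from scratch: it generates
eight synthetic sessions at the stated task statistics, runs the
cascaded model at `tau_S/tau_F = 600` plus a three-point timescale
sweep and a 100-repetition magnitude-shuffle null, prints the pipeline
summary, and writes the JSON result map to `--out`. All randomness
derives from `--seed`.

## Vignette

`vignettes/normadapt-methods.Rmd` documents the model assumptions, the
generator's stated world, the choice-readout construction (including
why a pure argmax readout is degenerate under uniform weights and how
the block-wise noise scale is estimated), numerical choices, and what
the synthetic-data tests do and do not establish.
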