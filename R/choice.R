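#' Readout configuration for model choices
#'
#' Controls how trial-by-trial choices are read out from fast-circuit
#' excitatory activity. The readout averages each option's `R^F` rate
#' over a window of the display period; the default window is the final
#' 200 ms of the display, the plateau region after the onset transient.
#'
#' Two choice channels are derived from the windowed rates. The
#' deterministic channel picks the option with the larger rate (`argmax`;
#' ties within `tie_epsilon` broken toward option a). The probabilistic
#' channel expresses choice stochasticity the way the circuit exposes
#' it: because the fast gain-control pool is shared between options
#' (all-ones weights), the sign of the plateau rate difference always
#' follows the sign of the value difference, so stochasticity lives not
#' in sign flips but in the trial-to-trial *reliability* of the rate
#' difference. Accordingly, the probability of choosing an option is a
#' base-10 logistic in the rate difference divided by the block's
#' trial-to-trial rate variability: blocks in which the value-coding
#' state fluctuates more produce flatter choice curves. The variability
#' (readout noise) of each block is estimated as the per-trial increment
#' standard deviation of the normalized-gain residuals across all
#' displayed trials (a diffusion estimate, robust to slow drift), and
#' scaled by the dimensionless factor `noise_gamma`.
#'
#' Because the network starts each session at the zero baseline, the
#' slow circuit spends roughly `3 * tau_slow` relaxing toward its
#' operating point; that deterministic ramp says nothing about the block
#' statistics, so trials inside the `burn_in` period are excluded from
#' the probabilistic channel (their argmax choice is still reported).
#'
#' @param window Length-2 numeric, readout window as offsets (ms) from
#'   display onset, or `NULL` (default) for the final 200 ms of each
#'   trial's display period.
#' @param rule Deterministic readout rule; only `"argmax"`.
#' @param tie_epsilon Rate differences at or below this magnitude count
#'   as ties (resolved toward option a).
#' @param noise_gamma Dimensionless readout-noise scale: the assumed
#'   choice noise is `noise_gamma` times the estimated per-trial state
#'   diffusion. The default (100) puts model choice-curve slopes in the
#'   same range as typical behavioral slopes (~1-2 per magnitude unit);
#'   block *contrasts* are insensitive to it away from saturation.
#' @param burn_in `"auto"` (default; `3 * tau_slow`, capped at half of
#'   the first block) or a time in ms excluded from the probabilistic
#'   channel at the session start.
#' @return A list of class `readout_config`.
#' @export
readout_config <- function(window = NULL, rule = "argmax",
                           tie_epsilon = 1e-12, noise_gamma = 100,
                           burn_in = "auto") {
  rule <- match.arg(rule, "argmax")
  if (!is.null(window)) {
    if (length(window) != 2 || window[2] <= window[1] || window[1] < 0) {
      abort("`window` must be increasing nonnegative offsets from onset.")
    }
  }
  if (tie_epsilon < 0) abort("`tie_epsilon` must be nonnegative.")
  if (noise_gamma <= 0) abort("`noise_gamma` must be positive.")
  if (!identical(burn_in, "auto") &&
      (!is.numeric(burn_in) || burn_in < 0)) {
    abort("`burn_in` must be \"auto\" or a nonnegative time in ms.")
  }
  structure(
    list(window = window, rule = rule, tie_epsilon = tie_epsilon,
         noise_gamma = noise_gamma, burn_in = burn_in),
    class = "readout_config"
  )
}

# per-trial readout window in session time
trial_windows <- function(session, cfg) {
  if (is.null(cfg$window)) {
    start <- session$display_on + session$display_duration - 200
    end <- session$display_on + session$display_duration
  } else {
    start <- session$display_on + cfg$window[1]
    end <- session$display_on + cfg$window[2]
    if (any(cfg$window[2] > session$display_duration)) {
      abort("Readout window extends beyond the display period.")
    }
  }
  cbind(start, end)
}

#' Windowed fast-circuit readout for one trial
#'
#' Averages each option's fast excitatory rate over the trial's readout
#' window of a recorded trajectory.
#'
#' @param trajectory An `nn_trajectory` with recorded samples covering
#'   the window.
#' @param trial A one-row slice of a session tibble.
#' @param cfg A [readout_config()].
#' @return Named numeric vector `c(r_a, r_b)`.
#' @export
readout <- function(trajectory, trial, cfg = readout_config()) {
  stopifnot(inherits(trajectory, "nn_trajectory"))
  if (is.null(trajectory$times)) {
    abort("Trajectory has no recorded samples; rerun with record_every > 0.")
  }
  w <- trial_windows(trial, cfg)
  keep <- trajectory$times >= w[1] - 1e-9 & trajectory$times < w[2] - 1e-9
  if (!any(keep)) {
    abort(sprintf(
      "Trial %d: readout window [%g, %g) not covered by the trajectory.",
      trial$trial, w[1], w[2]
    ))
  }
  m <- colMeans(trajectory$states[keep, c("r_fast_1", "r_fast_2"),
                                  drop = FALSE])
  c(r_a = unname(m[1]), r_b = unname(m[2]))
}

# block-wise readout-noise scale: per-trial increment SD of the
# normalized-gain residuals (level means removed within block)
block_noise_scales <- function(preds, v_a, v_b) {
  tibble::tibble(
    block = preds$block, trial = preds$trial,
    g_hat = (preds$r_a + preds$r_b) / (v_a + v_b),
    level = v_a + v_b, usable = !preds$in_burn_in
  ) |>
    dplyr::filter(.data$usable) |>
    dplyr::arrange(.data$trial) |>
    dplyr::mutate(
      u = .data$g_hat - stats::ave(.data$g_hat, .data$level),
      .by = "block"
    ) |>
    dplyr::summarise(
      sigma = if (dplyr::n() >= 3) {
        max(sd(diff(.data$u)) / sqrt(2), 1e-15)
      } else {
        NA_real_
      },
      n_noise = dplyr::n(),
      .by = "block"
    )
}

#' Predict model choices for a session
#'
#' Compiles the session into a value timeline, integrates the cascaded
#' network once over the whole session (state carried continuously
#' across trials and blocks, starting from the zero baseline), and
#' reads out every displayed trial: mean fast-circuit rates over the
#' readout window, their difference, the deterministic argmax choice,
#' and - for trials past the burn-in - the graded probability of
#' choosing option b obtained from the block-normalized rate difference
#' (see [readout_config()]). Aborted trials are read out (their options
#' were displayed and drive the network) but carry no argmax choice.
#'
#' @param session A session tibble.
#' @param params A [norm_params()].
#' @param cfg A [readout_config()].
#' @param dt Integration step, ms.
#' @param value_map Magnitude-to-value mapping (default identity).
#' @param init Initial state (default zero baseline).
#' @return A tibble with one row per trial: `trial`, `block`,
#'   `trial_type`, `aborted`, `mag_a`, `mag_b`, `mag_var` (variable
#'   magnitude, `mag_b`), `r_a`, `r_b`, `delta` (`r_a - r_b`),
#'   `choice` (`"a"`/`"b"`, `"none"` when aborted), `chose_var`,
#'   `p_var` (probability of choosing option b; `NA` inside the
#'   burn-in), `in_burn_in`. The per-block noise scales are attached as
#'   attribute `"noise_scales"` and the burn-in as `"burn_in_ms"`.
#' @examples
#' s <- generate_session(generator_config(trials_per_block = 15), seed = 8)
#' p <- predict_choices(s, norm_params(tau_ratio = 600))
#' attr(p, "noise_scales")
#' @export
predict_choices <- function(session, params = norm_params(),
                            cfg = readout_config(), dt = 1,
                            value_map = identity, init = NULL) {
  session <- validate_session(session)
  stopifnot(inherits(params, "norm_params"),
            inherits(cfg, "readout_config"))
  if (params$n_options != 2) {
    abort("Choice prediction requires a two-option network.")
  }
  timeline <- compile_value_timeline(session, value_map)
  win <- trial_windows(session, cfg)
  traj <- simulate_network(
    timeline, params, dt = dt, init = init, record_every = 0,
    windows = win
  )
  burn_in <- cfg$burn_in
  if (identical(burn_in, "auto")) {
    first_block <- session$block[1]
    b1 <- session[session$block == first_block, ]
    b1_end <- max(b1$display_on + b1$display_duration + b1$iti_after)
    burn_in <- min(3 * params$tau_slow, b1_end / 2)
  }
  r_a <- traj$window_means[, 1]
  r_b <- traj$window_means[, 2]
  delta <- r_a - r_b
  choice <- ifelse(session$aborted, "none",
                   ifelse(delta >= -cfg$tie_epsilon, "a", "b"))
  preds <- tibble::tibble(
    trial = session$trial,
    block = session$block,
    trial_type = session$trial_type,
    aborted = session$aborted,
    mag_a = session$mag_a,
    mag_b = session$mag_b,
    mag_var = session$mag_b,
    r_a = r_a, r_b = r_b, delta = delta,
    choice = choice,
    chose_var = ifelse(session$aborted, NA, choice == "b"),
    in_burn_in = session$display_on < burn_in
  )
  scales <- block_noise_scales(preds, value_map(session$mag_a),
                               value_map(session$mag_b))
  preds <- preds |>
    dplyr::left_join(scales, by = "block") |>
    dplyr::mutate(
      p_var = ifelse(
        .data$in_burn_in | is.na(.data$sigma), NA_real_,
        1 / (1 + 10^(-(.data$r_b - .data$r_a) /
                       (cfg$noise_gamma * .data$sigma)))
      )
    ) |>
    dplyr::select(-"sigma", -"n_noise")
  attr(preds, "noise_scales") <- scales
  attr(preds, "burn_in_ms") <- burn_in
  preds
}

#' Model slope contrast of one session
#'
#' Fits block-wise model choice curves to the probabilistic channel of
#' [predict_choices()] output (non-aborted test trials past the
#' burn-in) and contrasts narrow versus wide slopes.
#'
#' @param predictions Output of [predict_choices()].
#' @param ... Passed to [fit_choice_curve()].
#' @return One-row tibble as in [block_slope_difference()].
#' @export
model_slope_difference <- function(predictions, ...) {
  usable <- predictions |>
    dplyr::filter(.data$trial_type == "test", !.data$aborted,
                  !is.na(.data$p_var))
  if (nrow(usable) == 0) {
    abort("No usable test trials (all aborted or inside the burn-in).")
  }
  block_slope_difference(usable, mag_var, p_var, ...)
}
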