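#' Configuration for the synthetic session generator
#'
#' Describes a two-block (narrow/wide) choice session with the task's
#' statistical structure: ~60% adapter trials and 40% test trials per
#' block, test trials pairing a fixed reference reward against one of
#' five variable magnitudes, adapter trials pairing two independent
#' draws from a block-specific magnitude distribution with a common mean
#' but narrow versus wide standard deviation, inter-trial intervals
#' jittered uniformly on 600-900 ms, and aborted trials followed by a
#' time-out that lengthens the subsequent interval.
#'
#' Magnitudes live on a discrete grid (squares on the choice display);
#' the defaults put five test magnitudes symmetrically around a
#' reference of 5 on a 1-9 grid, with adapter distributions centered on
#' the same mean (5) and standard deviations of 1 (narrow) versus 3
#' (wide) before truncation to the grid.
#'
#' @param trials_per_block Trials in each block (default 289, the
#'   average block length in the task this emulates).
#' @param adapter_fraction Probability that a trial is an adapter trial
#'   (default 0.60).
#' @param test_magnitudes The five variable-reward magnitudes used on
#'   test trials.
#' @param reference_magnitude,reference_juice The fixed reference option
#'   on test trials (juice type A).
#' @param variable_juice Juice type of the variable and adapter rewards.
#' @param adapter_mean Common mean of both adapter distributions.
#' @param adapter_sd_narrow,adapter_sd_wide Standard deviations of the
#'   narrow and wide adapter distributions (narrow < wide).
#' @param magnitude_grid Allowed discrete magnitudes for adapter draws.
#' @param iti_range_ms Inter-trial-interval jitter range, ms.
#' @param abort_rate Probability a trial is aborted (default 0.15,
#'   i.e. 85% completed trials).
#' @param timeout_ms Time-out appended to the ITI after an aborted trial.
#' @param display_duration_ms Value-gate duration per trial: the choice
#'   display stays on through the 1200 ms fixation hold plus the
#'   saccade/target-hold epochs (default 2100 ms).
#' @param seed Default seed used by [generate_session()].
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(trials_per_block = 289,
                             adapter_fraction = 0.60,
                             test_magnitudes = c(3, 4, 5, 6, 7),
                             reference_magnitude = 5,
                             reference_juice = "A",
                             variable_juice = "B",
                             adapter_mean = 5,
                             adapter_sd_narrow = 1,
                             adapter_sd_wide = 3,
                             magnitude_grid = 1:9,
                             iti_range_ms = c(600, 900),
                             abort_rate = 0.15,
                             timeout_ms = 3000,
                             display_duration_ms = 2100,
                             seed = NULL) {
  if (length(test_magnitudes) == 0 || length(magnitude_grid) == 0) {
    abort("Magnitude lists must be non-empty.")
  }
  if (any(test_magnitudes <= 0) || any(magnitude_grid <= 0) ||
      reference_magnitude <= 0) {
    abort("Magnitudes must be positive.")
  }
  if (!(adapter_sd_narrow < adapter_sd_wide)) {
    abort("`adapter_sd_narrow` must be smaller than `adapter_sd_wide`.")
  }
  if (adapter_fraction < 0 || adapter_fraction > 1) {
    abort("`adapter_fraction` must be a probability.")
  }
  if (abort_rate < 0 || abort_rate > 1) {
    abort("`abort_rate` must be a probability.")
  }
  if (trials_per_block < 1) abort("`trials_per_block` must be positive.")
  if (length(iti_range_ms) != 2 || iti_range_ms[1] > iti_range_ms[2] ||
      iti_range_ms[1] < 0) {
    abort("`iti_range_ms` must be an increasing nonnegative pair.")
  }
  if (timeout_ms < 0) abort("`timeout_ms` must be nonnegative.")
  structure(
    list(
      trials_per_block = as.integer(trials_per_block),
      adapter_fraction = adapter_fraction,
      test_magnitudes = as.double(test_magnitudes),
      reference_magnitude = as.double(reference_magnitude),
      reference_juice = reference_juice,
      variable_juice = variable_juice,
      adapter_mean = adapter_mean,
      adapter_sd_narrow = adapter_sd_narrow,
      adapter_sd_wide = adapter_sd_wide,
      magnitude_grid = as.double(magnitude_grid),
      iti_range_ms = as.double(iti_range_ms),
      abort_rate = abort_rate,
      timeout_ms = as.double(timeout_ms),
      display_duration_ms = as.double(display_duration_ms),
      seed = seed
    ),
    class = "generator_config"
  )
}

# discretized truncated-Gaussian draw on the magnitude grid
draw_adapter_mags <- function(n, grid, mean, sd) {
  w <- dnorm(grid, mean = mean, sd = sd)
  if (sum(w) <= 0) w <- rep(1, length(grid))
  sample(grid, size = n, replace = TRUE, prob = w)
}

#' Generate a synthetic behavioral session
#'
#' Draws a full two-block session according to a [generator_config()]:
#' block order is randomized, trial identities are i.i.d.
#' adapter/test, test trials pair the fixed reference against one of the
#' five variable magnitudes (uniformly), adapter trials pair two
#' independent draws from the block's discretized truncated-Gaussian
#' magnitude distribution, ITIs are jittered uniformly (integer ms), and
#' aborted trials (no choice) append a time-out to their ITI. Choices
#' are left unset (`"none"`); see [synthetic_chooser()] for a stochastic
#' stand-in decision-maker.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed (overrides `config$seed`). Generation is
#'   fully reproducible per seed.
#' @return A validated session tibble with generator metadata attached.
#' @examples
#' s <- generate_session(generator_config(trials_per_block = 20), seed = 1)
#' dplyr::count(s, block, trial_type)
#' @export
generate_session <- function(config = generator_config(), seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  seed <- seed %||% config$seed
  with_seed_if(seed, {
    block_order <- sample(c("narrow", "wide"))
    per_block <- lapply(block_order, function(blk) {
      n <- config$trials_per_block
      is_adapter <- runif(n) < config$adapter_fraction
      sd_blk <- if (blk == "narrow") config$adapter_sd_narrow else
        config$adapter_sd_wide
      mag_a <- ifelse(is_adapter,
        draw_adapter_mags(n, config$magnitude_grid, config$adapter_mean,
                          sd_blk),
        config$reference_magnitude
      )
      mag_b <- ifelse(is_adapter,
        draw_adapter_mags(n, config$magnitude_grid, config$adapter_mean,
                          sd_blk),
        sample(config$test_magnitudes, n, replace = TRUE)
      )
      tibble::tibble(
        trial_type = ifelse(is_adapter, "adapter", "test"),
        block = blk,
        juice_a = ifelse(is_adapter, config$variable_juice,
                         config$reference_juice),
        mag_a = mag_a,
        juice_b = config$variable_juice,
        mag_b = mag_b,
        aborted = runif(n) < config$abort_rate
      )
    })
    trials <- dplyr::bind_rows(per_block)
    n_tot <- nrow(trials)
    itis <- sample(seq(config$iti_range_ms[1], config$iti_range_ms[2]),
                   n_tot + 1, replace = TRUE)
    trials <- trials |>
      dplyr::mutate(
        trial = seq_len(n_tot),
        display_duration = config$display_duration_ms,
        iti_after = itis[-1] + ifelse(.data$aborted, config$timeout_ms, 0),
        display_on = itis[1] +
          cumsum(dplyr::lag(.data$display_duration + .data$iti_after,
                            default = 0)),
        choice = "none"
      ) |>
      dplyr::select(dplyr::all_of(names(session_columns)))
    session <- validate_session(trials)
    session_meta(session) <- list(
      generator = unclass(config)[setdiff(names(config), "seed")],
      seed = seed,
      block_order = block_order
    )
    session
  })
}

#' Stochastic stand-in chooser
#'
#' Fills in choices for the non-aborted trials of a session using a
#' logistic (base-10) choice rule on the magnitude difference:
#' `P(choose a) = 1 / (1 + 10^((bias - (mag_a - mag_b)) * sensitivity))`.
#' On test trials (reference `a` versus variable `b` of magnitude `x`)
#' this yields a sigmoid choice curve in `x` with indifference point
#' `reference - bias` and slope `sensitivity`, which makes it a direct
#' ground truth for psychometric parameter recovery. It stands in for
#' animal behavior so the model-behavior analysis pipeline can run
#' without any empirical dataset.
#'
#' @param session A session tibble.
#' @param sensitivity Positive choice-curve slope, per magnitude unit.
#' @param bias Additive bias in magnitude units (positive favors b).
#' @param seed Integer seed for reproducible choices.
#' @return The session with its `choice` column filled for non-aborted
#'   trials.
#' @export
synthetic_chooser <- function(session, sensitivity = 1, bias = 0,
                              seed = NULL) {
  session <- validate_session(session)
  if (sensitivity <= 0) abort("`sensitivity` must be positive.")
  meta <- session_meta(session)
  with_seed_if(seed, {
    dmag <- session$mag_a - session$mag_b
    p_a <- 1 / (1 + 10^((bias - dmag) * sensitivity))
    pick <- ifelse(runif(nrow(session)) < p_a, "a", "b")
    session$choice <- ifelse(session$aborted, "none", pick)
  })
  session_meta(session) <- c(
    meta,
    list(chooser = list(sensitivity = sensitivity, bias = bias,
                        seed = seed))
  )
  session
}
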