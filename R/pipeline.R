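#' Configuration for an end-to-end analysis run
#'
#' Declares everything a full run needs: where sessions come from
#' (generated per [generator_config()] or loaded from files), the
#' network and readout settings, the stand-in chooser used for
#' synthetic behavior, optional timescale sweep and shuffle-null
#' stages, and a single root seed from which all randomness is derived
#' via named substreams.
#'
#' @param n_sessions Number of sessions to generate (ignored when
#'   `session_paths` is given).
#' @param generator A [generator_config()].
#' @param session_paths Optional character vector of session files to
#'   load instead of generating.
#' @param params A [norm_params()].
#' @param readout A [readout_config()].
#' @param dt Integration step, ms.
#' @param chooser List with `sensitivity` and `bias` for
#'   [synthetic_chooser()], or `NULL` if loaded sessions already carry
#'   choices.
#' @param sweep_ratios Optional timescale ratios for [tau_sweep()].
#' @param shuffle Optional list with `kind` (`"magnitude"`/`"iti"`) and
#'   `n_reps` for [shuffle_null()].
#' @param seed Root seed.
#' @param out_dir Optional output directory for CSV tables, a JSON
#'   summary and a run log.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_sessions = 4, generator = generator_config(),
                       session_paths = NULL, params = norm_params(),
                       readout = readout_config(), dt = 1,
                       chooser = list(sensitivity = 1, bias = 0),
                       sweep_ratios = NULL, shuffle = NULL, seed = 1,
                       out_dir = NULL) {
  if (is.null(session_paths) &&
      (is.null(n_sessions) || n_sessions < 1)) {
    abort("Provide either `session_paths` or a positive `n_sessions`.")
  }
  if (!is.null(shuffle) &&
      !all(c("kind", "n_reps") %in% names(shuffle))) {
    abort("`shuffle` must be a list with elements kind and n_reps.")
  }
  structure(
    list(
      n_sessions = n_sessions, generator = generator,
      session_paths = session_paths, params = params, readout = readout,
      dt = dt, chooser = chooser, sweep_ratios = sweep_ratios,
      shuffle = shuffle, seed = seed, out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' Run the full adaptation-analysis pipeline
#'
#' Generate-or-load sessions, fill in synthetic behavior (unless the
#' sessions already carry choices), simulate the network over every
#' session, fit block-wise choice curves for behavior and model,
#' contrast the slopes, test the mean adaptation effect, correlate
#' model and behavioral adaptation across sessions, and optionally run
#' the timescale sweep and shuffle-null stages. Every output is stamped
#' with the configuration hash and root seed; the same configuration
#' always yields the same result bundle.
#'
#' @param config A [run_config()].
#' @return A list of class `nn_run` with elements `sessions`,
#'   `per_session` (tibble of behavioral and model slope contrasts),
#'   `behavior_test`, `model_test` (mean-effect tests),
#'   `correlation`, `sign_agreement`, `sweep`, `shuffle`, `config`,
#'   `config_hash`, `seed`.
#' @examples
#' \donttest{
#' cfg <- run_config(
#'   n_sessions = 3,
#'   generator = generator_config(trials_per_block = 40),
#'   seed = 7
#' )
#' res <- run_pipeline(cfg)
#' res$per_session
#' }
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  config_hash <- rlang::hash(cfg_for_hash)
  say("run start (config %s, seed %s)", config_hash, seed)

  # --- sessions ---------------------------------------------------------
  if (!is.null(config$session_paths)) {
    sessions <- lapply(config$session_paths, read_session)
    say("loaded %d sessions", length(sessions))
  } else {
    sessions <- lapply(seq_len(config$n_sessions), function(i) {
      generate_session(config$generator, seed = derive_seed(seed, i))
    })
    say("generated %d sessions", length(sessions))
  }
  if (!is.null(config$chooser)) {
    sessions <- purrr::imap(sessions, function(s, i) {
      synthetic_chooser(
        s, sensitivity = config$chooser$sensitivity,
        bias = config$chooser$bias,
        seed = derive_seed(seed, 10000 + i)
      )
    })
    say("synthetic chooser applied (sensitivity %g, bias %g)",
        config$chooser$sensitivity, config$chooser$bias)
  }

  # --- per-session fits -------------------------------------------------
  per_session <- purrr::imap(sessions, function(s, i) {
    beh <- behavior_slope_difference(s)
    preds <- predict_choices(s, config$params, config$readout,
                             dt = config$dt)
    mod <- model_slope_difference(preds)
    tibble::tibble(
      session = i,
      behavior_diff = beh$norm_slope_diff,
      model_diff = mod$norm_slope_diff,
      s_narrow_behavior = beh$s_narrow, s_wide_behavior = beh$s_wide,
      s_narrow_model = mod$s_narrow, s_wide_model = mod$s_wide
    )
  }) |>
    dplyr::bind_rows()
  say("per-session contrasts done")

  behavior_test <- mean_effect_tests(per_session$behavior_diff,
                                     seed = derive_seed(seed, 21))
  model_test <- mean_effect_tests(per_session$model_diff,
                                  seed = derive_seed(seed, 22))
  correlation <- correlate_model_behavior(per_session$model_diff,
                                          per_session$behavior_diff)
  signs <- sign_agreement(per_session$model_diff,
                          per_session$behavior_diff)

  sweep <- NULL
  if (!is.null(config$sweep_ratios)) {
    say("timescale sweep over %d ratios", length(config$sweep_ratios))
    sweep <- tau_sweep(sessions, per_session$behavior_diff,
                       ratios = config$sweep_ratios,
                       params = config$params, cfg = config$readout,
                       dt = config$dt)
  }
  shuffle <- NULL
  if (!is.null(config$shuffle)) {
    say("%s shuffle null (%d reps)", config$shuffle$kind,
        config$shuffle$n_reps)
    shuffle <- shuffle_null(
      sessions, per_session$behavior_diff, kind = config$shuffle$kind,
      n_reps = config$shuffle$n_reps, params = config$params,
      cfg = config$readout, dt = config$dt,
      seed = derive_seed(seed, 31),
      observed_diffs = per_session$model_diff
    )
  }
  say("run complete")

  result <- structure(
    list(
      sessions = sessions, per_session = per_session,
      behavior_test = behavior_test, model_test = model_test,
      correlation = correlation, sign_agreement = signs,
      sweep = sweep, shuffle = shuffle, config = config,
      config_hash = config_hash, seed = seed, log = log_lines
    ),
    class = "nn_run"
  )

  if (!is.null(config$out_dir)) {
    write_run_outputs(result, config$out_dir)
  }
  result
}

write_run_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$per_session,
                   file.path(out_dir, "per_session.csv"))
  if (!is.null(result$sweep)) {
    readr::write_csv(dplyr::select(result$sweep, -"model_diffs"),
                     file.path(out_dir, "tau_sweep.csv"))
  }
  summary <- list(
    config_hash = result$config_hash,
    seed = result$seed,
    n_sessions = nrow(result$per_session),
    behavior_test = as.list(result$behavior_test),
    model_test = as.list(result$model_test),
    correlation = as.list(result$correlation),
    sign_agreement = as.list(result$sign_agreement),
    shuffle = if (!is.null(result$shuffle)) {
      as.list(tidy(result$shuffle))
    }
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  writeLines(result$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.nn_run <- function(x, ...) {
  cat(sprintf("<nn_run> %d sessions (config %s, seed %s)\n",
              nrow(x$per_session), x$config_hash, x$seed))
  cat(sprintf(
    "  behavior: mean norm slope diff %+.3f (t p = %.3g, perm p = %.3g)\n",
    x$behavior_test$mean_diff, x$behavior_test$p_t, x$behavior_test$p_perm
  ))
  cat(sprintf(
    "  model:    mean norm slope diff %+.3f (t p = %.3g, perm p = %.3g)\n",
    x$model_test$mean_diff, x$model_test$p_t, x$model_test$p_perm
  ))
  cat(sprintf("  model-behavior correlation r = %.3f (p = %.3g)\n",
              x$correlation$r, x$correlation$p))
  invisible(x)
}
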