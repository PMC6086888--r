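#' Mean adaptation-effect tests across sessions
#'
#' Tests whether per-session slope differences (narrow - wide) are
#' centered away from zero: a two-tailed one-sample t test plus a
#' non-parametric sign-flip permutation test. The permutation scheme
#' randomly flips the sign of each session's difference and compares
#' `|mean|` of each flipped sample to the observed `|mean|`; for
#' `n <= 20` sessions all `2^n` sign patterns are enumerated (exact p),
#' otherwise `n_perm` Monte Carlo flips are drawn and the p-value uses
#' the add-one correction `(b + 1) / (n_perm + 1)`.
#'
#' @param slope_diffs Numeric vector of per-session slope differences
#'   (at least 3).
#' @param n_perm Monte Carlo permutations when enumeration is not used.
#' @param seed Seed for the Monte Carlo path.
#' @return One-row tibble: `n`, `mean_diff`, `t`, `df`, `p_t`,
#'   `p_perm`, `perm_method`.
#' @export
mean_effect_tests <- function(slope_diffs, n_perm = 10000, seed = NULL) {
  d <- slope_diffs[is.finite(slope_diffs)]
  if (length(d) < 3) {
    abort("Need at least 3 sessions for the mean-effect tests.")
  }
  n <- length(d)
  if (sd(d) > 0) {
    tt <- t.test(d, mu = 0)
    t_stat <- unname(tt$statistic)
    p_t <- tt$p.value
  } else {
    # degenerate constant sample: zero mean is a perfect null fit,
    # nonzero mean is infinitely incompatible with it
    t_stat <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
    p_t <- if (mean(d) == 0) 1 else 0
  }
  obs <- abs(mean(d))
  if (n <= 20) {
    # exact enumeration of all sign patterns by repeated doubling
    sums <- 0
    for (di in d) sums <- c(sums + di, sums - di)
    p_perm <- mean(abs(sums / n) >= obs - 1e-12)
    method <- "exact"
  } else {
    p_perm <- with_seed_if(seed, {
      flips <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE),
                      nrow = n_perm)
      perm_means <- abs(as.vector(flips %*% d) / n)
      (sum(perm_means >= obs - 1e-12) + 1) / (n_perm + 1)
    })
    method <- "monte-carlo"
  }
  tibble::tibble(
    n = n, mean_diff = mean(d),
    t = t_stat, df = n - 1,
    p_t = p_t, p_perm = p_perm, perm_method = method
  )
}

#' Correlation between model and behavioral adaptation
#'
#' Pearson correlation (two-tailed) between per-session adaptation
#' effects in model-predicted and observed choice behavior.
#'
#' @param model_diffs,behavior_diffs Aligned per-session slope
#'   differences (>= 3 sessions).
#' @return One-row tibble: `r`, `df`, `p`, `n`.
#' @export
correlate_model_behavior <- function(model_diffs, behavior_diffs) {
  if (length(model_diffs) != length(behavior_diffs)) {
    abort("Model and behavior vectors must be aligned by session.")
  }
  ok <- is.finite(model_diffs) & is.finite(behavior_diffs)
  m <- model_diffs[ok]
  b <- behavior_diffs[ok]
  if (length(m) < 3) abort("Need at least 3 sessions.")
  if (var(m) == 0 || var(b) == 0) {
    warn("Zero variance in one of the vectors; correlation undefined.")
    return(tibble::tibble(r = NA_real_, df = length(m) - 2,
                          p = NA_real_, n = length(m)))
  }
  ct <- cor.test(m, b, method = "pearson")
  tibble::tibble(
    r = unname(ct$estimate), df = unname(ct$parameter),
    p = ct$p.value, n = length(m)
  )
}

#' Sign agreement between model and behavioral effects
#'
#' Chi-squared test of homogeneity on the direction (positive versus
#' non-positive) of per-session adaptation effects in model and
#' behavior; a non-significant result means the model's effect
#' directions are statistically indistinguishable from the behavioral
#' ones.
#'
#' @inheritParams correlate_model_behavior
#' @return One-row tibble: `chisq`, `df`, `p`, plus positive-sign counts.
#' @export
sign_agreement <- function(model_diffs, behavior_diffs) {
  ok <- is.finite(model_diffs) & is.finite(behavior_diffs)
  m <- model_diffs[ok] > 0
  b <- behavior_diffs[ok] > 0
  tab <- rbind(model = c(sum(m), sum(!m)),
               behavior = c(sum(b), sum(!b)))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(
    chisq = unname(ct$statistic), df = unname(ct$parameter),
    p = ct$p.value,
    n_pos_model = sum(m), n_pos_behavior = sum(b), n = length(m)
  )
}

# model slope contrasts for a list of sessions at given params
model_slope_diffs <- function(sessions, params, cfg, dt,
                              value_map = identity) {
  purrr::map_dbl(sessions, function(s) {
    tryCatch(
      {
        preds <- predict_choices(s, params, cfg, dt = dt,
                                 value_map = value_map)
        model_slope_difference(preds)$norm_slope_diff
      },
      error = function(e) {
        warn(paste0("Session skipped in model evaluation: ",
                    conditionMessage(e)))
        NA_real_
      }
    )
  })
}

#' Sweep the slow/fast timescale ratio
#'
#' Re-evaluates model-predicted adaptation at a grid of timescale
#' ratios `tau_slow / tau_fast`: for each ratio every session is
#' simulated, block-wise model choice curves are fitted, and the
#' per-session model slope differences are correlated with the supplied
#' behavioral slope differences. The default grid spans slow timescales
#' of 5-125 s at `tau_fast = 100` ms (ratios 50-1250), covering both
#' the one-trial and many-trial integration regimes.
#'
#' @param sessions List of session tibbles.
#' @param behavior_diffs Per-session behavioral slope differences,
#'   aligned with `sessions`.
#' @param ratios Timescale ratios to evaluate.
#' @param params Base [norm_params()]; `tau_slow` is overridden per
#'   ratio.
#' @param cfg A [readout_config()].
#' @param dt Integration step, ms.
#' @return A tibble of class `nn_tau_sweep`: one row per ratio with
#'   `ratio`, `tau_slow_ms`, `r`, `p`, `n`, and the per-session model
#'   differences as a list column `model_diffs`.
#' @export
tau_sweep <- function(sessions, behavior_diffs,
                      ratios = c(50, 100, 200, 400, 600, 750, 1000, 1250),
                      params = norm_params(), cfg = readout_config(),
                      dt = 1) {
  if (any(ratios <= 0)) abort("`ratios` must be positive.")
  if (length(sessions) != length(behavior_diffs)) {
    abort("`behavior_diffs` must align with `sessions`.")
  }
  rows <- purrr::map(ratios, function(rho) {
    p_rho <- norm_params(
      n_options = params$n_options, tau_fast = params$tau_fast,
      tau_slow = params$tau_fast * rho, omega = params$omega,
      alpha = params$alpha, beta = params$beta
    )
    md <- model_slope_diffs(sessions, p_rho, cfg, dt)
    ct <- correlate_model_behavior(md, behavior_diffs)
    dplyr::mutate(ct, ratio = rho, tau_slow_ms = params$tau_fast * rho,
                  model_diffs = list(md), .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("nn_tau_sweep", class(out))
  out
}

#' Permutation controls: magnitude and ITI shuffles
#'
#' `magnitude_shuffle()` permutes the sequence of trial contents (trial
#' type, option juices/magnitudes, abort flag and choice) across the
#' session's temporal slots while every slot keeps its original onset,
#' display duration, following ITI and block label - destroying the
#' reward sequence but retaining the session's temporal
#' characteristics. `iti_shuffle()` does the opposite: trial contents
#' stay in order, the inter-trial intervals (which include post-abort
#' time-outs) are permuted across trials, and onsets are recomputed
#' cumulatively - destroying timing while retaining the sequence.
#'
#' @param session A session tibble.
#' @param seed Integer seed for the permutation.
#' @param perm Optional explicit permutation of `seq_len(nrow(session))`
#'   (overrides `seed`); the identity permutation returns the session
#'   unchanged.
#' @return A session tibble of the same shape (same trial multiset and,
#'   for `iti_shuffle()`, the same total duration).
#' @export
magnitude_shuffle <- function(session, seed = NULL, perm = NULL) {
  session <- validate_session(session)
  meta <- session_meta(session)
  content_cols <- c("trial_type", "juice_a", "mag_a", "juice_b", "mag_b",
                    "aborted", "choice")
  perm <- check_perm(perm, nrow(session)) %||%
    with_seed_if(seed, sample(nrow(session)))
  out <- session
  out[content_cols] <- session[perm, content_cols]
  out <- validate_session(out)
  session_meta(out) <- c(meta, list(shuffle = list(kind = "magnitude",
                                                   seed = seed)))
  out
}

check_perm <- function(perm, n) {
  if (is.null(perm)) return(NULL)
  if (!setequal(perm, seq_len(n))) {
    abort("`perm` must be a permutation of the trial indices.")
  }
  as.integer(perm)
}

#' @rdname magnitude_shuffle
#' @export
iti_shuffle <- function(session, seed = NULL, perm = NULL) {
  session <- validate_session(session)
  meta <- session_meta(session)
  perm <- check_perm(perm, nrow(session)) %||%
    with_seed_if(seed, sample(nrow(session)))
  out <- session
  out$iti_after <- session$iti_after[perm]
  n <- nrow(out)
  if (n > 1) {
    out$display_on <- out$display_on[1] +
      cumsum(c(0, (out$display_duration + out$iti_after)[-n]))
  }
  out <- validate_session(out)
  session_meta(out) <- c(meta, list(shuffle = list(kind = "iti",
                                                   seed = seed)))
  out
}

#' Shuffle null distribution of model-behavior correlation
#'
#' Builds the null distribution of the model-behavior adaptation
#' correlation under repeated magnitude or ITI shuffles: each
#' repetition shuffles every session, re-runs the model, refits the
#' block choice curves, and recomputes the correlation with the (fixed)
#' behavioral slope differences. The two-sided empirical p-value is the
#' add-one-corrected fraction of null correlations at least as large in
#' magnitude as the observed one.
#'
#' @inheritParams tau_sweep
#' @param kind `"magnitude"` or `"iti"`.
#' @param n_reps Number of shuffle repetitions (>= 100 for a reportable
#'   p; smaller values run with a warning).
#' @param seed Root seed; each repetition and session uses a derived
#'   child seed.
#' @param observed_diffs Optional precomputed model slope differences
#'   for the unshuffled sessions (skips one model run).
#' @return Object of class `nn_shuffle_null`: list with `observed_r`,
#'   `null_r`, `p`, `kind`, `n_reps`, `n_sessions`, `seed`.
#' @export
shuffle_null <- function(sessions, behavior_diffs,
                         kind = c("magnitude", "iti"), n_reps = 1000,
                         params = norm_params(), cfg = readout_config(),
                         dt = 1, seed = NULL, observed_diffs = NULL) {
  kind <- match.arg(kind)
  if (n_reps <= 0) abort("`n_reps` must be positive.")
  if (n_reps < 100) {
    warn("Fewer than 100 shuffle repetitions; p-value is unreliable.")
  }
  shuffler <- switch(kind, magnitude = magnitude_shuffle,
                     iti = iti_shuffle)
  observed_diffs <- observed_diffs %||%
    model_slope_diffs(sessions, params, cfg, dt)
  obs_r <- correlate_model_behavior(observed_diffs, behavior_diffs)$r
  null_r <- purrr::map_dbl(seq_len(n_reps), function(rep) {
    shuffled <- purrr::imap(sessions, function(s, i) {
      shuffler(s, seed = derive_seed(seed, rep * 100003 + i))
    })
    md <- model_slope_diffs(shuffled, params, cfg, dt)
    correlate_model_behavior(md, behavior_diffs)$r
  })
  p <- (sum(abs(null_r) >= abs(obs_r), na.rm = TRUE) + 1) / (n_reps + 1)
  structure(
    list(
      observed_r = obs_r, null_r = null_r, p = p, kind = kind,
      n_reps = n_reps, n_sessions = length(sessions), seed = seed,
      observed_diffs = observed_diffs
    ),
    class = "nn_shuffle_null"
  )
}

#' @export
print.nn_shuffle_null <- function(x, ...) {
  cat(sprintf(
    "<nn_shuffle_null> %s shuffle, %d reps over %d sessions\n",
    x$kind, x$n_reps, x$n_sessions
  ))
  cat(sprintf(
    "  observed r = %.3f; null median r = %.3f; two-sided p = %.4g\n",
    x$observed_r, stats::median(x$null_r, na.rm = TRUE), x$p
  ))
  invisible(x)
}

#' @export
tidy.nn_shuffle_null <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, observed_r = x$observed_r,
    null_median = stats::median(x$null_r, na.rm = TRUE),
    null_q025 = stats::quantile(x$null_r, 0.025, na.rm = TRUE,
                                names = FALSE),
    null_q975 = stats::quantile(x$null_r, 0.975, na.rm = TRUE,
                                names = FALSE),
    p = x$p, n_reps = x$n_reps
  )
}
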