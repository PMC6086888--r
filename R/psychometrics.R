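choice_curve_fun <- function(x, x50, s) 1 / (1 + 10^((x50 - x) * s))

#' Fit a sigmoid choice curve
#'
#' Fits the standard psychometric sigmoid
#' `y(x) = 1 / (1 + 10^((x50 - x) * s))` to two-alternative choice data:
#' the probability of choosing the variable option as a function of its
#' magnitude `x`. `x50` is the indifference point (magnitude of equal
#' choice probability) and `s` the slope, the measure of overall choice
#' sensitivity (its inverse reflects choice stochasticity).
#'
#' The default objective is least squares on the per-level choice
#' proportions; `objective = "binomial"` instead maximizes the Bernoulli
#' likelihood over trials. Responses may be 0/1 choices or graded
#' probabilities in `[0, 1]` (e.g. model choice probabilities); graded
#' responses are averaged per level exactly like choices. The optimizer
#' is initialized at the level whose proportion is nearest 0.5 with a
#' slope from a base-10 logit line fit, and the slope is constrained to
#' `[0, s_max]`. Fits where the data give the sigmoid no foothold (all
#' responses on one side, or the slope pinned at a bound) are flagged
#' `boundary = TRUE` rather than silently returned.
#'
#' @param data Data frame of test-trial responses.
#' @param magnitude,response Columns (tidy-eval) holding the variable
#'   magnitude and the chose-variable indicator or probability.
#' @param objective `"ls"` (default; least squares on per-level
#'   proportions) or `"binomial"` (Bernoulli likelihood).
#' @param s_max Upper bound for the slope, per magnitude unit. The
#'   default 10 means a curve rising from 0.1 to 0.9 over ~0.2
#'   magnitude units - effectively a step on the task's unit-spaced
#'   magnitude grid.
#' @return An object of class `choice_curve_fit` with components `x50`,
#'   `s`, `rmse` (between fitted curve and per-level proportions),
#'   `n_trials`, `levels` (per-level proportions), `boundary`,
#'   `objective`. Supports [tidy()], [glance()], `predict()`,
#'   [autoplot()].
#' @examples
#' x <- rep(c(3, 4, 5, 6, 7), each = 40)
#' p <- 1 / (1 + 10^((5 - x) * 1.2))
#' fit_choice_curve(data.frame(mag = x, chose = p),
#'                  magnitude = mag, response = chose)
#' @export
fit_choice_curve <- function(data, magnitude = mag_var,
                             response = chose_var,
                             objective = c("ls", "binomial"),
                             s_max = 10) {
  objective <- match.arg(objective)
  x <- dplyr::pull(data, {{ magnitude }})
  y <- as.double(dplyr::pull(data, {{ response }}))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) == 0) abort("No usable choice data.")
  if (any(y < 0 | y > 1)) {
    abort("`response` must be 0/1 choices or probabilities in [0, 1].")
  }
  levels <- tibble::tibble(x = x, y = y) |>
    dplyr::summarise(p = mean(.data$y), n = dplyr::n(),
                     .by = "x") |>
    dplyr::arrange(.data$x)
  if (nrow(levels) < 2) {
    abort("Need choices at >= 2 distinct magnitudes to fit a curve.")
  }

  # initialization: x50 at the level nearest 0.5, slope from a base-10
  # logit line on clipped proportions
  x50_0 <- levels$x[which.min(abs(levels$p - 0.5))]
  p_clip <- pmin(pmax(levels$p, 0.01), 0.99)
  lgt <- log10(p_clip / (1 - p_clip))
  s_0 <- if (nrow(levels) > 1 && var(levels$x) > 0) {
    max(min(coef(stats::lm(lgt ~ levels$x))[2], s_max), 1e-3)
  } else {
    1
  }

  obj <- if (objective == "ls") {
    function(par) {
      yhat <- choice_curve_fun(levels$x, par[1], par[2])
      sum((levels$p - yhat)^2)
    }
  } else {
    function(par) {
      ph <- pmin(pmax(choice_curve_fun(x, par[1], par[2]), 1e-12),
                 1 - 1e-12)
      -sum(y * log(ph) + (1 - y) * log(1 - ph))
    }
  }
  span <- diff(range(levels$x))
  fit <- optim(
    c(x50_0, s_0), obj, method = "L-BFGS-B",
    lower = c(min(levels$x) - 5 * span, 0),
    upper = c(max(levels$x) + 5 * span, s_max),
    control = list(factr = 1e3, maxit = 500)
  )
  x50 <- fit$par[1]
  s <- fit$par[2]
  yhat <- choice_curve_fun(levels$x, x50, s)
  one_sided <- all(levels$p >= 0.5) || all(levels$p <= 0.5)
  boundary <- (s >= s_max - 1e-8) || one_sided
  structure(
    list(
      x50 = x50, s = s,
      rmse = sqrt(mean((levels$p - yhat)^2)),
      n_trials = length(x),
      levels = levels,
      boundary = boundary,
      objective = objective,
      s_max = s_max,
      convergence = fit$convergence
    ),
    class = "choice_curve_fit"
  )
}

#' @export
print.choice_curve_fit <- function(x, ...) {
  cat(sprintf(
    "<choice_curve_fit> x50 = %.4g, slope = %.4g (rmse %.3g, n = %d%s)\n",
    x$x50, x$s, x$rmse, x$n_trials,
    if (x$boundary) ", boundary" else ""
  ))
  invisible(x)
}

#' @export
predict.choice_curve_fit <- function(object, magnitude, ...) {
  choice_curve_fun(magnitude, object$x50, object$s)
}

#' Tidy a choice-curve fit
#'
#' @param x A `choice_curve_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter (`x50`, `s`); `glance()`:
#'   a one-row fit summary.
#' @export
tidy.choice_curve_fit <- function(x, ...) {
  tibble::tibble(
    term = c("x50", "s"),
    estimate = c(x$x50, x$s)
  )
}

#' @rdname tidy.choice_curve_fit
#' @export
glance.choice_curve_fit <- function(x, ...) {
  tibble::tibble(
    x50 = x$x50, s = x$s, rmse = x$rmse, n_trials = x$n_trials,
    boundary = x$boundary, objective = x$objective
  )
}

#' Block-contrast of choice-curve slopes
#'
#' Contrasts the fitted choice-curve slopes of the narrow and wide
#' blocks of one session. The normalized difference
#' `(s_narrow - s_wide) / (s_narrow + s_wide)` is the adaptation-effect
#' measure: positive values mean sharper (less stochastic) choices in
#' the narrow block, the direction predicted by efficient coding. The
#' raw difference is also reported.
#'
#' @param narrow,wide `choice_curve_fit` objects (or bare slopes).
#' @return One-row tibble: `s_narrow`, `s_wide`, `slope_diff`,
#'   `norm_slope_diff`.
#' @export
slope_difference <- function(narrow, wide) {
  s_n <- if (inherits(narrow, "choice_curve_fit")) narrow$s else narrow
  s_w <- if (inherits(wide, "choice_curve_fit")) wide$s else wide
  total <- s_n + s_w
  nd <- if (!is.finite(total) || total <= 0) {
    warn("Slope sum is not positive; normalized difference undefined.")
    NA_real_
  } else {
    (s_n - s_w) / total
  }
  tibble::tibble(
    s_narrow = s_n, s_wide = s_w,
    slope_diff = s_n - s_w,
    norm_slope_diff = nd
  )
}

#' Per-block choice curves and slope contrast
#'
#' Fits one choice curve per block to test-trial responses and returns
#' the block contrast. Works on monkey-style choices (`chose_var`
#' logical) and on model choice probabilities (`p_var`) alike.
#'
#' @param data Test-trial data with a `block` column.
#' @param magnitude,response Columns passed to [fit_choice_curve()].
#' @param ... Passed to [fit_choice_curve()].
#' @return One-row tibble from [slope_difference()], with `x50_narrow`,
#'   `x50_wide`, `rmse_narrow`, `rmse_wide` appended and the two fits
#'   attached as an attribute `"fits"`.
#' @export
block_slope_difference <- function(data, magnitude = mag_var,
                                   response = chose_var, ...) {
  if (!"block" %in% names(data)) abort("`data` must have a block column.")
  fits <- lapply(c(narrow = "narrow", wide = "wide"), function(blk) {
    sub <- dplyr::filter(data, .data$block == blk)
    if (nrow(sub) == 0) {
      abort(sprintf("No test-trial data in the %s block.", blk))
    }
    fit_choice_curve(sub, {{ magnitude }}, {{ response }}, ...)
  })
  out <- slope_difference(fits$narrow, fits$wide) |>
    dplyr::mutate(
      x50_narrow = fits$narrow$x50, x50_wide = fits$wide$x50,
      rmse_narrow = fits$narrow$rmse, rmse_wide = fits$wide$rmse,
      boundary = fits$narrow$boundary | fits$wide$boundary
    )
  attr(out, "fits") <- fits
  out
}

#' Behavioral slope contrast of one session
#'
#' Convenience wrapper: selects the session's non-aborted, chosen test
#' trials and contrasts narrow- versus wide-block choice-curve slopes
#' of the recorded choices.
#'
#' @param session A session tibble with choices filled in.
#' @param ... Passed to [fit_choice_curve()].
#' @return One-row tibble as in [block_slope_difference()].
#' @export
behavior_slope_difference <- function(session, ...) {
  session <- validate_session(session)
  tests <- session |>
    dplyr::filter(.data$trial_type == "test", !.data$aborted,
                  .data$choice != "none") |>
    dplyr::mutate(mag_var = .data$mag_b,
                  chose_var = .data$choice == "b")
  if (nrow(tests) == 0) abort("Session has no chosen test trials.")
  block_slope_difference(tests, ...)
}
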