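#' Time derivatives of the cascaded normalization network
#'
#' Right-hand side of the coupled rate equations. Each fast gain-control
#' unit relaxes toward the omega-weighted sum of fast excitatory rates
#' plus the alpha-weighted sum of slow excitatory rates; each excitatory
#' unit relaxes toward its value input divisively scaled by its paired
#' gain unit, `V_i / (1 + G_i)`. The slow circuit has the same recurrent
#' structure (weights `beta`) but runs on `tau_slow`. All derivatives are
#' scaled by the corresponding time constant.
#'
#' @param state A [norm_state].
#' @param values Length-`N` nonnegative value-input vector.
#' @param params A [norm_params].
#' @return A `norm_state` holding `d(state)/dt`.
#' @examples
#' p <- norm_params(tau_fast = 1)
#' norm_derivs(norm_state(2), c(20, 0), p)
#' @export
norm_derivs <- function(state, values, params) {
  stopifnot(inherits(state, "norm_state"), inherits(params, "norm_params"))
  values <- check_values(values, params)
  n <- params$n_options
  if (length(state$r_fast) != n) {
    abort("`state` dimension does not match `params$n_options`.")
  }
  dg_fast <- (-state$g_fast + drop(params$omega %*% state$r_fast) +
                drop(params$alpha %*% state$r_slow)) / params$tau_fast
  dr_fast <- (-state$r_fast + values / (1 + state$g_fast)) / params$tau_fast
  dg_slow <- (-state$g_slow + drop(params$beta %*% state$r_slow)) /
    params$tau_slow
  dr_slow <- (-state$r_slow + values / (1 + state$g_slow)) / params$tau_slow
  norm_state(r_fast = dr_fast, g_fast = dg_fast,
             r_slow = dr_slow, g_slow = dg_slow)
}

#' Single classical Runge-Kutta (RK4) step
#'
#' Advances the network state from `t` to `t + dt` under the value inputs
#' of `timeline`, using the classical fourth-order Runge-Kutta scheme.
#' Exposed mainly for step-size studies and as a reference for the
#' compiled integrator used by [simulate_network()].
#'
#' @param state A [norm_state].
#' @param t Current time, ms.
#' @param dt Step size, ms (positive; `t + dt` must lie inside the
#'   timeline).
#' @param timeline A [value_timeline].
#' @param params A [norm_params].
#' @return The updated `norm_state` at `t + dt`.
#' @export
rk4_step <- function(state, t, dt, timeline, params) {
  stopifnot(inherits(timeline, "value_timeline"))
  if (dt <= 0) abort("`dt` must be positive.")
  if (t + dt > timeline$breaks[length(timeline$breaks)] + 1e-9) {
    abort("`t + dt` lies outside the timeline.")
  }
  # value inputs are piecewise constant and steps are assumed not to
  # straddle segment boundaries (enforced by simulate_network), so all
  # four stages see the value at the step start; sampling the next
  # segment for the final stage would cost an order of accuracy at
  # every discontinuity
  v1 <- drop(timeline_value(timeline, t))
  v2 <- v1
  v3 <- v1
  add <- function(s, k, h) {
    norm_state(
      r_fast = s$r_fast + h * k$r_fast, g_fast = s$g_fast + h * k$g_fast,
      r_slow = s$r_slow + h * k$r_slow, g_slow = s$g_slow + h * k$g_slow
    )
  }
  k1 <- norm_derivs(state, v1, params)
  k2 <- norm_derivs(add(state, k1, dt / 2), v2, params)
  k3 <- norm_derivs(add(state, k2, dt / 2), v2, params)
  k4 <- norm_derivs(add(state, k3, dt), v3, params)
  out <- norm_state(
    r_fast = state$r_fast +
      dt / 6 * (k1$r_fast + 2 * k2$r_fast + 2 * k3$r_fast + k4$r_fast),
    g_fast = state$g_fast +
      dt / 6 * (k1$g_fast + 2 * k2$g_fast + 2 * k3$g_fast + k4$g_fast),
    r_slow = state$r_slow +
      dt / 6 * (k1$r_slow + 2 * k2$r_slow + 2 * k3$r_slow + k4$r_slow),
    g_slow = state$g_slow +
      dt / 6 * (k1$g_slow + 2 * k2$g_slow + 2 * k3$g_slow + k4$g_slow)
  )
  if (any(!is.finite(unlist(out)))) {
    abort(sprintf("Integration failure: non-finite state at t = %g.", t))
  }
  out
}

check_grid_alignment <- function(timeline, dt) {
  rel <- (timeline$breaks - timeline$breaks[1]) / dt
  if (any(abs(rel - round(rel)) > 1e-6)) {
    abort(paste0(
      "`dt` must divide every timeline segment boundary so that ",
      "Runge-Kutta steps never straddle a value discontinuity."
    ))
  }
}

#' Simulate the network over a value timeline
#'
#' Integrates the cascaded normalization equations over the full
#' timeline with fixed-step RK4 (compiled code by default). The state is
#' carried continuously across trials and blocks; nothing is reset at
#' trial boundaries. Setting `engine = "R"` runs a plain-R loop over
#' [rk4_step()] - orders of magnitude slower, intended for cross-checks.
#'
#' @param timeline A [value_timeline].
#' @param params A [norm_params].
#' @param dt Integration step, ms; must divide every segment boundary.
#'   The default 1 ms matches the millisecond-level evaluation of the
#'   behavioral analyses.
#' @param init Initial [norm_state]; all-zero baseline by default.
#' @param record_every Record the state every this many steps (1 = every
#'   step). `0` disables trajectory recording (useful with `windows`).
#' @param windows Optional two-column matrix (start, end in ms) of
#'   non-overlapping readout windows; mean fast-circuit excitatory rates
#'   over each window are returned without storing the full trajectory.
#' @param engine `"cpp"` (default) or `"R"`.
#' @return An object of class `nn_trajectory`: a list with `times`,
#'   `states` (matrix, one row per recorded sample, columns
#'   `r_fast_i, g_fast_i, r_slow_i, g_slow_i`), `window_means`,
#'   `final_state`, plus the simulation settings.
#' @examples
#' sc <- scenario_block_steps(trials_per_block = 4)
#' traj <- simulate_network(sc$timeline, sc$params, dt = 0.05)
#' @export
simulate_network <- function(timeline, params, dt = 1, init = NULL,
                             record_every = 1L, windows = NULL,
                             engine = c("cpp", "R")) {
  stopifnot(inherits(timeline, "value_timeline"),
            inherits(params, "norm_params"))
  engine <- match.arg(engine)
  n <- params$n_options
  if (timeline$n_options != n) {
    abort("Timeline and params disagree on the number of options.")
  }
  if (dt <= 0) abort("`dt` must be positive.")
  check_grid_alignment(timeline, dt)
  init <- init %||% norm_state(n)
  if (any(unlist(init) < 0)) abort("`init` must be nonnegative.")
  if (!is.null(windows)) {
    windows <- matrix(as.double(windows), ncol = 2)
    o <- order(windows[, 1])
    sorted <- windows[o, , drop = FALSE]
    overlap <- nrow(sorted) > 1 &&
      any(sorted[-1, 1] < sorted[-nrow(sorted), 2] - 1e-9)
    if (any(windows[, 2] <= windows[, 1]) || overlap) {
      abort("`windows` must be non-overlapping with end > start.")
    }
    if (any(windows < timeline$breaks[1] - 1e-9) ||
        any(windows > timeline$breaks[length(timeline$breaks)] + 1e-9)) {
      abort("`windows` must lie inside the timeline.")
    }
  }
  if (engine == "cpp") {
    win <- windows %||% matrix(numeric(0), ncol = 2)
    o <- order(win[, 1])
    res <- nn_integrate_cpp(
      breaks = timeline$breaks, seg_values = timeline$values, dt = dt,
      tau_fast = params$tau_fast, tau_slow = params$tau_slow,
      omega = params$omega, alpha = params$alpha, beta = params$beta,
      init = state_to_vector(init),
      win_start = win[o, 1], win_end = win[o, 2],
      record_every = as.integer(record_every)
    )
    states <- res$trajectory
    win_mean <- if (is.null(windows)) NULL else {
      m <- matrix(NA_real_, nrow = length(o), ncol = n)
      m[o, ] <- res$win_mean
      m
    }
    final_state <- vector_to_state(res$final_state, n)
  } else {
    res <- simulate_network_r(timeline, params, dt, init, record_every,
                              windows)
    states <- res$trajectory
    win_mean <- res$win_mean
    final_state <- res$final_state
  }
  times <- NULL
  if (!is.null(states)) {
    times <- states[, 1]
    states <- states[, -1, drop = FALSE]
    colnames(states) <- c(
      paste0("r_fast_", 1:n), paste0("g_fast_", 1:n),
      paste0("r_slow_", 1:n), paste0("g_slow_", 1:n)
    )
  }
  if (!is.null(win_mean)) colnames(win_mean) <- paste0("r_fast_", 1:n)
  structure(
    list(
      times = times, states = states, window_means = win_mean,
      final_state = final_state, n_options = n, dt = dt,
      params = params
    ),
    class = "nn_trajectory"
  )
}

# Pure-R integration loop; reference path for the compiled integrator.
simulate_network_r <- function(timeline, params, dt, init, record_every,
                               windows) {
  t0 <- timeline$breaks[1]
  t_end <- timeline$breaks[length(timeline$breaks)]
  n_steps <- round((t_end - t0) / dt)
  n <- params$n_options
  state <- init
  rec <- record_every > 0
  traj <- if (rec) {
    matrix(NA_real_, nrow = floor(n_steps / record_every) + 1,
           ncol = 1 + 4 * n)
  }
  if (rec) traj[1, ] <- c(t0, state_to_vector(state))
  row <- 1L
  n_win <- if (is.null(windows)) 0L else nrow(windows)
  win_sum <- matrix(0, nrow = max(n_win, 1), ncol = n)
  win_n <- integer(max(n_win, 1))
  accum <- function(t_now) {
    if (n_win == 0) return(invisible())
    hit <- which(t_now >= windows[, 1] - 1e-9 & t_now < windows[, 2] - 1e-9)
    if (length(hit) == 1) {
      win_sum[hit, ] <<- win_sum[hit, ] + state$r_fast
      win_n[hit] <<- win_n[hit] + 1L
    }
  }
  accum(t0)
  for (step in seq_len(n_steps)) {
    t_now <- t0 + (step - 1) * dt
    state <- rk4_step(state, t_now, dt, timeline, params)
    if (rec && step %% record_every == 0) {
      row <- row + 1L
      traj[row, ] <- c(t0 + step * dt, state_to_vector(state))
    }
    accum(t0 + step * dt)
  }
  list(
    trajectory = traj,
    win_mean = if (n_win > 0) sweep(win_sum, 1, pmax(win_n, 1), "/"),
    final_state = state
  )
}

#' @export
print.nn_trajectory <- function(x, ...) {
  cat(sprintf(
    "<nn_trajectory> %d options, dt = %g ms%s%s\n",
    x$n_options, x$dt,
    if (!is.null(x$times)) {
      sprintf(", %d samples over %g ms", length(x$times),
              max(x$times) - min(x$times))
    } else ", no recorded samples",
    if (!is.null(x$window_means)) {
      sprintf(", %d readout windows", nrow(x$window_means))
    } else ""
  ))
  invisible(x)
}

#' @export
as_tibble.nn_trajectory <- function(x, ...) {
  if (is.null(x$states)) {
    abort("Trajectory was run with `record_every = 0`; nothing to tabulate.")
  }
  tibble::as_tibble(x$states) |>
    dplyr::mutate(time = x$times, .before = 1)
}

#' Steady state of the network under constant value input
#'
#' Solves the fixed point of the cascaded equations for a constant input
#' `V`. The slow subsystem is autonomous (it does not see the fast
#' circuit), so its fixed point is found first by damped fixed-point
#' iteration on `R^S = V / (1 + beta R^S)`; the fast fixed point is then
#' solved the same way with the slow drive held at its equilibrium. If
#' the iteration stalls, a long forward integration (100 slow time
#' constants) is used as a fallback.
#'
#' @param values Length-`N` nonnegative constant value input.
#' @param params A [norm_params].
#' @param tol Convergence tolerance on successive iterates.
#' @param max_iter Iteration cap before the integration fallback.
#' @return A [norm_state] at equilibrium, with attribute `"residual"`
#'   giving the maximum absolute time derivative at the solution.
#' @examples
#' # one option, all-ones weights, V = 20:
#' # slow: R (1 + R) = 20        => R = (-1 + sqrt(81)) / 2 = 4
#' # fast: R (1 + R + 4) = 20    => R = (-5 + sqrt(105)) / 2
#' steady_state(20, norm_params(n_options = 1))
#' @export
steady_state <- function(values, params, tol = 1e-13,
                         max_iter = 100000L) {
  stopifnot(inherits(params, "norm_params"))
  values <- check_values(values, params)
  n <- params$n_options

  solve_stage <- function(w, extra) {
    r <- values / (1 + extra) # ignore recurrent term for the start
    for (i in seq_len(max_iter)) {
      r_new <- 0.5 * r + 0.5 * values / (1 + drop(w %*% r) + extra)
      if (max(abs(r_new - r)) < tol) {
        return(pmax(r_new, 0))
      }
      r <- r_new
    }
    NULL
  }

  r_slow <- solve_stage(params$beta, 0)
  r_fast <- if (!is.null(r_slow)) {
    solve_stage(params$omega, drop(params$alpha %*% r_slow))
  }
  if (is.null(r_slow) || is.null(r_fast)) {
    # fallback: relax the full system for a long time
    tl <- value_timeline(0, 100 * params$tau_slow, matrix(values, 1))
    traj <- simulate_network(tl, params, dt = params$tau_fast / 10,
                             record_every = 0)
    st <- traj$final_state
  } else {
    st <- norm_state(
      r_fast = r_fast,
      g_fast = drop(params$omega %*% r_fast) +
        drop(params$alpha %*% r_slow),
      r_slow = r_slow,
      g_slow = drop(params$beta %*% r_slow)
    )
  }
  resid <- max(abs(unlist(norm_derivs(st, values, params))))
  scale <- max(1, max(abs(unlist(st)))) /
    min(params$tau_fast, params$tau_slow)
  if (resid > 1e-6 * scale) {
    abort(sprintf(
      "Steady-state solver did not converge (residual %.3g).", resid
    ))
  }
  attr(st, "residual") <- resid
  st
}

#' Block-stepped demonstration scenario
#'
#' Builds the canonical two-option demonstration: option 1's value steps
#' through a set of levels across consecutive blocks (each block a train
#' of identical trials with value gated on then off), while option 2's
#' value is constant; time constants default to 1 (fast) and 1000 (slow)
#' in arbitrary units. This input structure exposes both the fast
#' within-trial transients and the slow across-trial drift of the
#' cascaded circuit.
#'
#' @param v_steps Values that option 1 steps through, one per block.
#' @param v_fixed Constant value of option 2.
#' @param n_cycles How many times the full step sequence repeats.
#' @param trials_per_block Trials per block.
#' @param on_duration,off_duration Per-trial gate durations (time units).
#' @param tau_fast,tau_slow Time constants (same units).
#' @return A list with elements `timeline` ([value_timeline]), `params`
#'   ([norm_params]) and `trials` (tibble of per-trial onsets/blocks).
#' @export
scenario_block_steps <- function(v_steps = c(20, 40, 60), v_fixed = 40,
                                 n_cycles = 2, trials_per_block = 20,
                                 on_duration = 3, off_duration = 1,
                                 tau_fast = 1, tau_slow = 1000) {
  blocks <- rep(rep(seq_along(v_steps), each = trials_per_block), n_cycles)
  v1 <- rep(rep(v_steps, each = trials_per_block), n_cycles)
  n_tr <- length(v1)
  period <- on_duration + off_duration
  onsets <- (seq_len(n_tr) - 1) * period
  timeline <- value_timeline(
    onsets = onsets, durations = on_duration,
    values = cbind(v1, rep(v_fixed, n_tr)),
    total_duration = n_tr * period
  )
  list(
    timeline = timeline,
    params = norm_params(n_options = 2, tau_fast = tau_fast,
                         tau_slow = tau_slow),
    trials = tibble::tibble(
      trial = seq_len(n_tr), block = blocks, v1 = v1, v2 = v_fixed,
      onset = onsets, offset = onsets + on_duration
    )
  )
}
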