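# Independent reference implementations used as oracles. These are coded
# directly from the model definitions and share no code with the package
# internals they check.

# Single-circuit normalization network (the fast-only model): N paired
# excitatory/inhibitory units, one time constant, no slow input. Plain-R
# fixed-step RK4 over a piecewise-constant input, value held at the step
# start (steps are grid-aligned).
oracle_single_circuit <- function(breaks, seg_values, dt, tau, omega,
                                  r0, g0, record_every = 1) {
  n_steps <- round((max(breaks) - breaks[1]) / dt)
  r <- r0
  g <- g0
  seg_of <- function(t) {
    idx <- findInterval(t, breaks, rightmost.closed = TRUE)
    min(max(idx, 1), nrow(seg_values))
  }
  deriv <- function(r, g, v) {
    list(
      dr = (-r + v / (1 + g)) / tau,
      dg = (-g + as.vector(omega %*% r)) / tau
    )
  }
  out_t <- numeric(0)
  out <- NULL
  push <- function(t, r, g) {
    out_t <<- c(out_t, t)
    out <<- rbind(out, c(r, g))
  }
  push(breaks[1], r, g)
  for (step in seq_len(n_steps)) {
    t <- breaks[1] + (step - 1) * dt
    v <- seg_values[seg_of(t), ]
    k1 <- deriv(r, g, v)
    k2 <- deriv(r + dt / 2 * k1$dr, g + dt / 2 * k1$dg, v)
    k3 <- deriv(r + dt / 2 * k2$dr, g + dt / 2 * k2$dg, v)
    k4 <- deriv(r + dt * k3$dr, g + dt * k3$dg, v)
    r <- r + dt / 6 * (k1$dr + 2 * k2$dr + 2 * k3$dr + k4$dr)
    g <- g + dt / 6 * (k1$dg + 2 * k2$dg + 2 * k3$dg + k4$dg)
    if (step %% record_every == 0) push(breaks[1] + step * dt, r, g)
  }
  list(times = out_t, states = out) # columns r_1..r_N, g_1..g_N
}

# closed-form fixed points for one option, all-ones weights:
# slow:  R (1 + R) = V
# fast:  R (1 + R + R_slow) = V
oracle_fixed_point_1d <- function(v) {
  r_slow <- (-1 + sqrt(1 + 4 * v)) / 2
  c_slow <- r_slow
  r_fast <- (-(1 + c_slow) + sqrt((1 + c_slow)^2 + 4 * v)) / 2
  list(r_slow = r_slow, r_fast = r_fast)
}

# the psychometric sigmoid, written out independently
oracle_sigmoid <- function(x, x50, s) 1 / (1 + 10^((x50 - x) * s))

# small session generator config for fast tests
tiny_config <- function(trials_per_block = 20, ...) {
  generator_config(trials_per_block = trials_per_block, ...)
}

# hand-built minimal valid session (2 trials per block)
tiny_session <- function() {
  s <- tibble::tibble(
    trial = 1:4,
    trial_type = c("adapter", "test", "test", "adapter"),
    block = c("narrow", "narrow", "wide", "wide"),
    juice_a = c("B", "A", "A", "B"),
    mag_a = c(4, 5, 5, 6),
    juice_b = "B",
    mag_b = c(6, 3, 7, 2),
    display_on = c(700, 3700, 6700, 9700),
    display_duration = 2100,
    iti_after = c(900, 900, 900, 600),
    aborted = FALSE,
    choice = c("a", "b", "a", "b")
  )
  validate_session(s)
}
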