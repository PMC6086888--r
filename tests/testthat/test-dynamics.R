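test_that("parameter and state constructors enforce their invariants", {
  p <- norm_params()
  expect_equal(p$n_options, 2L)
  expect_equal(p$tau_slow / p$tau_fast, 600)
  expect_true(all(p$omega == 1) && all(p$alpha == 1) && all(p$beta == 1))

  expect_error(norm_params(tau_fast = -1), "tau_fast")
  expect_error(norm_params(tau_ratio = 0), "tau_ratio")
  expect_error(norm_params(omega = matrix(1, 3, 3)), "omega")
  expect_error(norm_params(alpha = -0.5), "alpha")

  st <- norm_state(3)
  expect_equal(lengths(unclass(st)), c(r_fast = 3L, g_fast = 3L,
                                       r_slow = 3L, g_slow = 3L))
  expect_error(norm_state(r_fast = c(1, 2), g_fast = 1,
                          r_slow = c(0, 0), g_slow = c(0, 0)), "g_fast")
})

test_that("derivatives match direct substitution into the rate equations", {
  p <- norm_params(tau_fast = 1, tau_ratio = 600)

  # global fixed point at V = 0
  d0 <- norm_derivs(norm_state(2), c(0, 0), p)
  expect_equal(unlist(d0), unlist(norm_state(2)), ignore_attr = TRUE)

  # zero state, V = (20, 0): dR^F = V / tau_F, dG^F = 0, dR^S = V / tau_S
  d <- norm_derivs(norm_state(2), c(20, 0), p)
  expect_equal(d$r_fast, c(20, 0))
  expect_equal(d$g_fast, c(0, 0))
  expect_equal(d$r_slow, c(20 / 600, 0))
  expect_equal(d$g_slow, c(0, 0))

  # derivative vanishes at the closed-form one-option fixed point
  fp <- oracle_fixed_point_1d(20)
  p1 <- norm_params(n_options = 1)
  st <- norm_state(
    r_fast = fp$r_fast, g_fast = fp$r_fast + fp$r_slow,
    r_slow = fp$r_slow, g_slow = fp$r_slow
  )
  dd <- norm_derivs(st, 20, p1)
  expect_lt(max(abs(unlist(dd))), 1e-9)

  # contract violations
  expect_error(norm_derivs(norm_state(2), c(1, 2, 3), p), "length")
  expect_error(norm_derivs(norm_state(2), c(-1, 0), p), "nonnegative")
})

test_that("rk4_step is exact at the origin and fourth-order accurate", {
  p <- norm_params(tau_fast = 1, tau_ratio = 1000)
  tl <- value_timeline(0, 10, c(0, 0))
  st <- rk4_step(norm_state(2), 0, 0.5, tl, p)
  expect_identical(unlist(st), unlist(norm_state(2)))

  # constant input: halving dt shrinks the local error ~16x against a
  # much finer reference
  tl2 <- value_timeline(0, 10, c(30, 10))
  step_to <- function(dt, t_end) {
    s <- norm_state(2)
    for (k in seq_len(round(t_end / dt))) {
      s <- rk4_step(s, (k - 1) * dt, dt, tl2, p)
    }
    unlist(s)
  }
  ref <- step_to(1 / 64, 1)
  e1 <- max(abs(step_to(1 / 4, 1) - ref))
  e2 <- max(abs(step_to(1 / 8, 1) - ref))
  expect_gt(e1 / e2, 10)
  expect_lt(e1 / e2, 24)

  expect_error(rk4_step(norm_state(2), 9.9, 0.5, tl2, p), "outside")
})

test_that("time rescaling of (tau, dt) leaves the trajectory invariant", {
  sc <- scenario_block_steps(trials_per_block = 3, n_cycles = 1)
  base <- simulate_network(sc$timeline, sc$params, dt = 0.05)
  c_fac <- 4
  tl2 <- value_timeline(
    onsets = sc$trials$onset * c_fac,
    durations = (sc$trials$offset - sc$trials$onset) * c_fac,
    values = cbind(sc$trials$v1, sc$trials$v2),
    total_duration = sc$timeline$duration * c_fac
  )
  p2 <- norm_params(tau_fast = sc$params$tau_fast * c_fac,
                    tau_slow = sc$params$tau_slow * c_fac)
  scaled <- simulate_network(tl2, p2, dt = 0.05 * c_fac)
  expect_equal(scaled$states, base$states, tolerance = 1e-12)
})

test_that("with alpha = 0 the fast circuit reproduces an independent
           single-circuit integrator", {
  sc <- scenario_block_steps(trials_per_block = 5, n_cycles = 1)
  p0 <- norm_params(n_options = 2, tau_fast = 1, tau_slow = 1000,
                    alpha = 0)
  traj <- simulate_network(sc$timeline, p0, dt = 0.05,
                           record_every = 20)
  ora <- oracle_single_circuit(
    breaks = sc$timeline$breaks, seg_values = sc$timeline$values,
    dt = 0.05, tau = 1, omega = matrix(1, 2, 2),
    r0 = c(0, 0), g0 = c(0, 0), record_every = 20
  )
  expect_equal(traj$times, ora$times)
  expect_lt(max(abs(traj$states[, 1:4] - ora$states)), 1e-10)
})

test_that("trajectories stay nonnegative from nonnegative initial states", {
  for (seed in 1:3) {
    set.seed(seed)
    v <- matrix(runif(6, 0, 60), ncol = 2)
    tl <- value_timeline(onsets = c(0, 5, 10), durations = 4, values = v,
                         total_duration = 15)
    p <- norm_params(tau_fast = 1, tau_ratio = 10^runif(1, 0, 3))
    tr <- simulate_network(tl, p, dt = 0.05)
    expect_gte(min(tr$states), -1e-9)
  }
})

test_that("steady_state matches the closed-form quadratics and V = 0", {
  p1 <- norm_params(n_options = 1)
  st <- steady_state(20, p1)
  expect_equal(st$r_slow, 4, tolerance = 1e-9)
  expect_equal(st$r_fast, (-5 + sqrt(105)) / 2, tolerance = 1e-6)
  expect_lt(attr(st, "residual"), 1e-9)

  st0 <- steady_state(c(0, 0), norm_params())
  expect_equal(unlist(st0), unlist(norm_state(2)), ignore_attr = TRUE,
               tolerance = 1e-12)

  # long simulation converges to the fixed point
  p <- norm_params(tau_fast = 1, tau_slow = 50)
  tl <- value_timeline(0, 2000, c(30, 10))
  tr <- simulate_network(tl, p, dt = 0.1, record_every = 0)
  ss <- steady_state(c(30, 10), p)
  expect_equal(unlist(tr$final_state), unlist(ss), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("steady-state output neurons are normalized by the other option", {
  p <- norm_params()
  v_grid <- seq(5, 50, length.out = 10)
  r1 <- outer(v_grid, v_grid, Vectorize(function(v1, v2) {
    steady_state(c(v1, v2), p)$r_fast[1]
  }))
  # increasing in own value (rows), decreasing in the other (columns)
  expect_true(all(diff(r1) > 0))
  expect_true(all(t(diff(t(r1))) < 0))
})

test_that("cpp and R engines agree and windows match trajectory averages", {
  sc <- scenario_block_steps(trials_per_block = 3, n_cycles = 1)
  win <- cbind(c(1, 6), c(3, 8))
  t_cpp <- simulate_network(sc$timeline, sc$params, dt = 0.1,
                            windows = win)
  t_r <- simulate_network(sc$timeline, sc$params, dt = 0.1,
                          windows = win, engine = "R")
  expect_identical(t_cpp$states, t_r$states)
  expect_equal(t_cpp$window_means, t_r$window_means, tolerance = 1e-12)
  expect_equal(unlist(t_cpp$final_state), unlist(t_r$final_state))

  # window means equal the mean of recorded samples over [start, end)
  keep <- t_cpp$times >= 1 & t_cpp$times < 3
  expect_equal(
    unname(t_cpp$window_means[1, ]),
    unname(colMeans(t_cpp$states[keep, c("r_fast_1", "r_fast_2")]))
  )
})

test_that("misaligned steps and bad windows are rejected", {
  tl <- value_timeline(0, 7, c(10, 10))
  p <- norm_params(tau_fast = 1)
  expect_error(simulate_network(tl, p, dt = 3), "divide")
  expect_error(simulate_network(tl, p, dt = 1,
                                windows = cbind(1, 10)), "inside")
  expect_error(simulate_network(tl, p, dt = 1,
                                windows = cbind(c(1, 2), c(3, 4))),
               "overlap")
})
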