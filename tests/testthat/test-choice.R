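test_that("windowed readout averages fast-circuit rates", {
  # constant trajectory: readout returns the constant rates
  p <- norm_params()
  # start at the exact fixed point so the trajectory is constant
  ss <- steady_state(c(30, 10), p)
  tl2 <- value_timeline(0, 5000, c(30, 10))
  traj <- simulate_network(tl2, p, dt = 1, init = ss)
  trial <- tibble::tibble(trial = 1L, display_on = 1000,
                          display_duration = 2100)
  r <- readout(traj, trial, readout_config())
  expect_equal(unname(r), ss$r_fast, tolerance = 1e-6)

  # symmetric inputs with symmetric weights: identical readouts
  tl3 <- value_timeline(500, 2600, c(25, 25), total_duration = 4000)
  traj3 <- simulate_network(tl3, p, dt = 1)
  r3 <- readout(traj3, tibble::tibble(trial = 1L, display_on = 500,
                                      display_duration = 2600))
  expect_lt(abs(r3["r_a"] - r3["r_b"]), 1e-9)

  expect_error(
    readout(traj3, tibble::tibble(trial = 7L, display_on = 3800,
                                  display_duration = 2100)),
    "Trial 7"
  )
})

test_that("predicted choices are deterministic and magnitude-consistent", {
  s <- generate_session(tiny_config(trials_per_block = 25), seed = 51)
  p1 <- predict_choices(s, norm_params(tau_ratio = 600))
  p2 <- predict_choices(s, norm_params(tau_ratio = 600))
  expect_identical(p1, p2) # bit-exact pure function

  expect_equal(nrow(p1), nrow(s)) # every displayed trial read out
  expect_true(all(p1$choice[p1$aborted] == "none"))

  # with the shared gain pool, the plateau argmax follows the sign of
  # the value difference on non-tied test trials
  tests <- p1[p1$trial_type == "test" & !p1$aborted &
                p1$mag_var != p1$mag_a, ]
  expect_true(all(tests$choice == ifelse(tests$mag_var > tests$mag_a,
                                         "b", "a")))

  # graded channel: probabilities increase with variable magnitude
  lv <- tapply(p1$p_var[p1$trial_type == "test" & !p1$aborted &
                          !p1$in_burn_in],
               p1$mag_var[p1$trial_type == "test" & !p1$aborted &
                            !p1$in_burn_in], mean)
  expect_true(all(diff(lv[order(as.numeric(names(lv)))]) > 0))

  # burn-in trials carry no probability
  expect_true(all(is.na(p1$p_var[p1$in_burn_in])))
  expect_true(all(!is.na(p1$p_var[!p1$in_burn_in])))
})

test_that("readout values depend on the adapter context of the past", {
  # same final test trial after low- versus high-value adapter history
  make_session <- function(adapter_mag) {
    n <- 30
    iti <- rep(750, n)
    dur <- rep(2100, n)
    on <- 700 + cumsum(c(0, (dur + iti)[-n]))
    tibble::tibble(
      trial = seq_len(n),
      trial_type = c(rep("adapter", n - 2), "test", "test"),
      block = rep(c("narrow", "wide"), each = n / 2),
      juice_a = c(rep("B", n - 2), "A", "A"),
      mag_a = c(rep(adapter_mag, n - 2), 5, 5),
      juice_b = "B",
      mag_b = c(rep(adapter_mag, n - 2), 6, 6),
      display_on = on, display_duration = dur, iti_after = iti,
      aborted = FALSE, choice = "none"
    ) |> validate_session()
  }
  cfg <- readout_config(burn_in = 0)
  lo <- predict_choices(make_session(2), norm_params(tau_ratio = 300),
                        cfg)
  hi <- predict_choices(make_session(8), norm_params(tau_ratio = 300),
                        cfg)
  # richer adapter history -> stronger normalization -> lower rates and
  # smaller rate differences on the identical test trial
  last_lo <- lo[nrow(lo), ]
  last_hi <- hi[nrow(hi), ]
  expect_lt(last_hi$r_a, last_lo$r_a)
  expect_lt(abs(last_hi$delta), abs(last_lo$delta))
})

test_that("model_slope_difference needs usable test trials", {
  s <- generate_session(tiny_config(trials_per_block = 25), seed = 52)
  preds <- predict_choices(s, norm_params(tau_ratio = 600))
  out <- model_slope_difference(preds)
  expect_true(is.finite(out$norm_slope_diff))
  expect_error(
    model_slope_difference(preds[preds$trial_type == "adapter", ]),
    "test trials"
  )
})
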