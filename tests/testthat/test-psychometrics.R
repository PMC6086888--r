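test_that("noiseless sigmoid data are inverted essentially exactly", {
  x <- c(3, 4, 5, 6, 7)
  cases <- list(c(x50 = 3, s = 1.2), c(x50 = 5, s = 0.6),
                c(x50 = 5.5, s = 2.5))
  for (truth in cases) {
    dat <- data.frame(mag = x,
                      p = oracle_sigmoid(x, truth["x50"], truth["s"]))
    fit <- fit_choice_curve(dat, mag, p)
    expect_equal(fit$x50, unname(truth["x50"]), tolerance = 1e-6)
    expect_equal(fit$s, unname(truth["s"]), tolerance = 1e-6)
    expect_lt(fit$rmse, 1e-7)
    # the fitted curve passes through 0.5 at x50 by construction
    expect_equal(predict(fit, fit$x50), 0.5)
  }
})

test_that("degenerate choice patterns are flagged, not silently fitted", {
  x <- rep(c(3, 4, 5, 6, 7), each = 20)
  # flat data: slope near zero
  flat <- data.frame(mag = x, chose = rep(c(TRUE, FALSE), 50))
  f <- fit_choice_curve(flat, mag, chose)
  expect_lt(f$s, 0.05)

  # all choices on one side: boundary flag
  one_sided <- data.frame(mag = x, chose = TRUE)
  f2 <- fit_choice_curve(one_sided, mag, chose)
  expect_true(f2$boundary)

  # perfect separation: slope capped at s_max and flagged
  step_dat <- data.frame(mag = x, chose = x > 5)
  f3 <- fit_choice_curve(step_dat, mag, chose, s_max = 10)
  expect_true(f3$boundary)
  expect_lte(f3$s, 10)

  expect_error(fit_choice_curve(data.frame(mag = rep(3, 5),
                                           chose = c(0, 1, 0, 1, 0)),
                                mag, chose), "distinct")
  expect_error(fit_choice_curve(data.frame(mag = x, chose = 2), mag,
                                chose), "probabilities")
})

test_that("fitted curves are monotone and tidy methods are consistent", {
  x <- rep(c(3, 4, 5, 6, 7), each = 30)
  set.seed(7)
  dat <- data.frame(mag = x,
                    chose = runif(length(x)) <
                      oracle_sigmoid(x, 5, 1.1))
  fit <- fit_choice_curve(dat, mag, chose)
  grid <- seq(2, 8, by = 0.1)
  expect_true(all(diff(predict(fit, grid)) > 0))

  td <- tidy(fit)
  expect_equal(td$term, c("x50", "s"))
  expect_equal(td$estimate, c(fit$x50, fit$s))
  gl <- glance(fit)
  expect_equal(gl$n_trials, nrow(dat))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("binomial-likelihood fitting recovers the same curve", {
  x <- rep(c(3, 4, 5, 6, 7), each = 60)
  set.seed(11)
  dat <- data.frame(mag = x,
                    chose = runif(length(x)) <
                      oracle_sigmoid(x, 4.8, 1.4))
  f_ls <- fit_choice_curve(dat, mag, chose)
  f_ml <- fit_choice_curve(dat, mag, chose, objective = "binomial")
  expect_equal(f_ml$x50, f_ls$x50, tolerance = 0.2)
  expect_equal(f_ml$s, f_ls$s, tolerance = 0.3)
})

test_that("parameter recovery from the synthetic chooser is accurate", {
  # scaled-down version of the full acceptance check: 40 replicates
  set.seed(13)
  errs <- t(replicate(40, {
    s <- generate_session(
      generator_config(trials_per_block = 300, abort_rate = 0),
      seed = sample.int(1e6, 1)
    )
    s <- synthetic_chooser(s, sensitivity = 1, bias = 0,
                           seed = sample.int(1e6, 1))
    fit <- behavior_slope_difference(s)
    c(x50 = mean(c(fit$x50_narrow, fit$x50_wide)) - 5,
      s = mean(c(fit$s_narrow, fit$s_wide)) - 1)
  }))
  expect_lt(median(abs(errs[, "x50"])), 0.25)
  expect_lt(median(abs(errs[, "s"])), 0.2)
})

test_that("slope contrasts follow their definition", {
  expect_equal(slope_difference(2, 2)$norm_slope_diff, 0)
  expect_equal(slope_difference(2, 1)$norm_slope_diff, 1 / 3)
  # antisymmetry
  expect_equal(slope_difference(1, 2)$norm_slope_diff, -1 / 3)
  expect_equal(slope_difference(2, 1)$slope_diff, 1)
  expect_warning(out <- slope_difference(0, 0), "undefined")
  expect_true(is.na(out$norm_slope_diff))
})
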