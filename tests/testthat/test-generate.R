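test_that("generation is reproducible and schema-valid", {
  cfg <- tiny_config(trials_per_block = 40)
  s1 <- generate_session(cfg, seed = 5)
  s2 <- generate_session(cfg, seed = 5)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_silent(validate_session(s1))
  s3 <- generate_session(cfg, seed = 6)
  expect_false(identical(s1$mag_b, s3$mag_b))

  expect_error(generator_config(test_magnitudes = numeric(0)),
               "non-empty")
  expect_error(generator_config(adapter_sd_narrow = 3,
                                adapter_sd_wide = 1), "smaller")
  expect_error(generator_config(adapter_fraction = 1.2), "probability")
})

test_that("trial composition matches the task's statistical structure", {
  s <- generate_session(generator_config(trials_per_block = 5000),
                        seed = 31)
  # i.i.d. test/adapter identity: test fraction within 2% of 40%
  expect_equal(mean(s$trial_type == "test"), 0.40, tolerance = 0.05)

  # test trials: constant reference vs one of five magnitudes
  tests <- s[s$trial_type == "test", ]
  expect_true(all(tests$mag_a == 5) && all(tests$juice_a == "A"))
  expect_setequal(unique(tests$mag_b), c(3, 4, 5, 6, 7))

  # adapters: wide block spreads more, means within 2 SEM
  ad <- s[s$trial_type == "adapter", ]
  mags <- split(c(ad$mag_a, ad$mag_b), rep(ad$block, 2))
  expect_gt(sd(mags$wide), sd(mags$narrow))
  sem <- sqrt(var(mags$wide) / length(mags$wide) +
                var(mags$narrow) / length(mags$narrow))
  expect_lt(abs(mean(mags$wide) - mean(mags$narrow)), 2 * sem)

  # ITIs jittered on the configured range (plus time-outs after aborts)
  base_iti <- s$iti_after - ifelse(s$aborted, 3000, 0)
  expect_true(all(base_iti >= 600 & base_iti <= 900))
  expect_equal(mean(s$aborted), 0.15, tolerance = 0.035)

  # both blocks present, contiguous, order random across seeds
  orders <- vapply(1:8, function(i) {
    generate_session(tiny_config(5), seed = i)$block[1]
  }, "")
  expect_setequal(unique(orders), c("narrow", "wide"))
})

test_that("the synthetic chooser follows its logistic rule", {
  cfg <- generator_config(trials_per_block = 2500)
  s <- generate_session(cfg, seed = 41)
  s <- synthetic_chooser(s, sensitivity = 1, bias = 0, seed = 42)

  tests <- s[s$trial_type == "test" & !s$aborted, ]
  # equal magnitudes: choice rate near 0.5
  tie <- tests[tests$mag_b == 5, ]
  expect_equal(mean(tie$choice == "a"), 0.5, tolerance = 0.06)
  # level-wise choice rates follow the base-10 logistic in delta-mag
  p_hat <- tapply(tests$choice == "b", tests$mag_b, mean)
  p_true <- 1 / (1 + 10^((5 - as.numeric(names(p_hat)))))
  expect_equal(as.vector(p_hat), as.vector(p_true), tolerance = 0.08)

  # aborted trials never carry a choice
  expect_true(all(s$choice[s$aborted] == "none"))
  # near-infinite sensitivity: deterministic by magnitude
  s_det <- synthetic_chooser(s, sensitivity = 1000, seed = 43)
  det <- s_det[s_det$trial_type == "test" & !s_det$aborted &
                 s_det$mag_b != 5, ]
  expect_true(all(det$choice == ifelse(det$mag_b > 5, "b", "a")))

  expect_error(synthetic_chooser(s, sensitivity = 0), "positive")
})
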