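# Monte-Carlo ensembles, sweeps and trend fitting.

test_that("ensembles are reproducible and tidy/glance behave", {
  spec <- ensemble_spec(small_cfg(target_relative_density = 8e-4),
                        n_samples = 2, master_seed = 21)
  e1 <- run_ensemble(spec)
  e2 <- run_ensemble(spec)
  expect_identical(e1$samples$modulus, e2$samples$modulus)
  expect_equal(NROW(tidy(e1)), 2)
  g <- glance(e1)
  expect_equal(g$n, 2)
  expect_true(is.finite(g$mean) && is.finite(g$sd))
})

test_that("sweep grids are honoured and per-point summaries returned", {
  spec <- ensemble_spec(small_cfg(target_relative_density = 8e-4),
                        n_samples = 2, master_seed = 5,
                        sweep_variable = "crosslink_fraction",
                        sweep_values = c(0.5, 1))
  res <- run_ensemble(spec)
  expect_equal(sort(unique(res$samples$sweep_value)), c(0.5, 1))
  expect_equal(NROW(res$summary), 2)
  # the ten-point filament length grid of the length study
  lens <- seq(0.6, 6, by = 0.6)
  spec2 <- ensemble_spec(generation_config(seed = 1), n_samples = 2,
                         master_seed = 1,
                         sweep_variable = "filament_length",
                         sweep_values = lens)
  expect_equal(length(spec2$sweep_values), 10)
  # perfectly correlated std: sd = 0.2 * mean after applying the sweep
  pt <- actinform:::apply_sweep(spec2$base_config, "filament_length", 2.4)
  expect_equal(pt$cfg$filament_length_std, 0.48)
})

test_that("linear trend fitting matches closed forms", {
  # exactly collinear points
  f <- fit_linear_trend(1:4, 2 + 3 * (1:4))
  expect_equal(f$slope, 3)
  expect_equal(f$r_squared, 1)
  # constant response: zero slope
  f0 <- fit_linear_trend(1:4, rep(2, 4))
  expect_equal(f0$slope, 0)
  # the reported density-study means are very nearly linear in density
  f2 <- fit_linear_trend(c(0.15, 0.20, 0.25, 0.30), c(3.11, 4.38, 5.69, 6.83))
  expect_gt(f2$r_squared, 0.99)
  expect_error(fit_linear_trend(c(1, 1, 1), c(1, 2, 3)), "degenerate")
})

test_that("derived seeds stay in 32-bit range and differ across samples", {
  s <- sapply(1:50, function(i) actinform:::derive_seed(1e9, 3, i))
  expect_true(all(s > 0 & s < 2^31))
  expect_false(any(duplicated(s)))
})
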