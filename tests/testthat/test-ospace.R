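test_that("degenerate Monte Carlo reproduces deterministic acceptance", {
  pm0 <- perturbation_model(sd = c(filling_level = 0, rotational_speed = 0,
                                   blending_time = 0),
                            residual_noise = FALSE, draws = 50)
  ok <- failure_probability(ref_fits, ref_specs,
                            list(filling_level = 32, rotational_speed = 24,
                                 blending_time = 24), pm0, seed = 1)
  expect_equal(ok$probability, 0)
  bad <- failure_probability(ref_fits, ref_specs,
                             list(filling_level = 70, rotational_speed = 25,
                                  blending_time = 9), pm0, seed = 1)
  expect_equal(bad$probability, 1)
  # whole-map equality with the design space
  grid <- list(filling_level = seq(30, 70, 5),
               rotational_speed = seq(15, 25, 2.5))
  pin <- list(blending_time = 24)
  om <- operating_space_map(ref_fits, ref_specs, grid = grid, fixed = pin,
                            perturbation = pm0, seed = 3)
  ds <- design_space(ref_fits, ref_specs, grid = grid, fixed = pin)
  expect_equal(om$operating, ds$acceptable)
  # alpha = 1 accepts the whole grid
  om1 <- operating_space_map(ref_fits, ref_specs, grid = grid,
                             fixed = pin, perturbation = pm0, alpha = 1,
                             seed = 3)
  expect_true(all(om1$operating))
})

test_that("operating region shrinks monotonically with setpoint noise", {
  grid <- list(filling_level = seq(30, 70, 5),
               rotational_speed = seq(15, 25, 2.5))
  pin <- list(blending_time = 24)
  sizes <- vapply(c(0.02, 0.05, 0.10), function(frac) {
    om <- operating_space_map(
      ref_fits, ref_specs, grid = grid, fixed = pin,
      perturbation = perturbation_model(default_frac = frac,
                                        residual_noise = FALSE,
                                        draws = 2000),
      seed = 11)
    sum(om$operating)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_gt(sizes[1], 0)
})

test_that("the operating space at 24 min is wider than at earlier times", {
  grid <- list(filling_level = seq(30, 70, 5),
               rotational_speed = seq(15, 25, 2.5))
  pm <- perturbation_model(draws = 2000)
  n24 <- sum(operating_space_map(ref_fits, ref_specs, grid = grid,
             fixed = list(blending_time = 24), perturbation = pm,
             seed = 5)$operating)
  n9 <- sum(operating_space_map(ref_fits, ref_specs, grid = grid,
            fixed = list(blending_time = 9), perturbation = pm,
            seed = 5)$operating)
  expect_gt(n24, 0)
  expect_lte(n9, n24)
})

test_that("failure probability matches the Gaussian tail in the linear case", {
  runs <- synth_doe(c(intercept = 0, x1 = 1), noise_sd = 0)
  lf <- fit_rsm(runs, "y", terms = "x1")
  fp <- failure_probability(
    list(y = lf), list(y = spec_limits(upper = 1.645)),
    setpoint = list(filling_level = 50, rotational_speed = 20,
                    blending_time = 16.5),
    perturbation_model(sd = c(filling_level = 20), default_frac = 0,
                       residual_noise = FALSE, draws = 50000,
                       truncate = FALSE),
    seed = 2)
  p_true <- pnorm(1.645, lower.tail = FALSE)
  expect_lt(abs(fp$probability - p_true), 3 * sqrt(p_true * (1 - p_true) /
                                                   50000))
})

test_that("identical seeds give identical probability surfaces", {
  grid <- list(filling_level = seq(30, 70, 10),
               rotational_speed = c(15, 20, 25))
  pm <- perturbation_model(draws = 500)
  a <- operating_space_map(ref_fits, ref_specs, grid = grid,
                           fixed = list(blending_time = 24),
                           perturbation = pm, seed = 99)
  b <- operating_space_map(ref_fits, ref_specs, grid = grid,
                           fixed = list(blending_time = 24),
                           perturbation = pm, seed = 99)
  expect_identical(a$failure_probability, b$failure_probability)
})
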