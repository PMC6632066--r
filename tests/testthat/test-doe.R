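test_that("factor coding maps low/center/high to -1/0/+1", {
  f <- blending_factors()
  expect_equal(code_factors(data.frame(filling_level = 50,
                                       rotational_speed = 20,
                                       blending_time = 16.5), f),
               data.frame(x1 = 0, x2 = 0, x3 = 0))
  expect_equal(code_factors(data.frame(filling_level = 32,
                                       rotational_speed = 24,
                                       blending_time = 24), f),
               data.frame(x1 = -0.9, x2 = 0.8, x3 = 1))
  expect_warning(code_factors(data.frame(filling_level = 90,
                                         rotational_speed = 20,
                                         blending_time = 16.5), f),
                 "extrapolation")
  nat <- decode_factors(data.frame(x1 = -0.9, x2 = 0.8, x3 = 1), f)
  expect_equal(unlist(nat), c(filling_level = 32, rotational_speed = 24,
                              blending_time = 24))
  expect_error(factor_def("bad", 5, 5), "low < center < high")
})

test_that("3-factor Box-Behnken construction yields the canonical run set", {
  f <- blending_factors()
  d <- build_bbd(f, center_runs = 3, seed = 42)
  expect_equal(nrow(d), 15L)
  coded <- d[, c("x1", "x2", "x3")]
  # 12 edge midpoints: exactly one zero among the non-center runs
  noncenter <- coded[rowSums(coded == 0) == 1, ]
  expect_equal(nrow(noncenter), 12L)
  expect_equal(sum(rowSums(coded == 0) == 3), 3L)
  # multiset of coded rows matches the bundled 15-run table's coded settings
  t3 <- code_factors(fx$runs[, c("filling_level", "rotational_speed",
                                 "blending_time")], f)
  key <- function(m) sort(apply(m, 1, paste, collapse = ","))
  expect_equal(key(coded), key(t3))
  # seed changes order, not content
  d2 <- build_bbd(f, center_runs = 3, seed = 7)
  expect_equal(key(d2[, c("x1", "x2", "x3")]), key(coded))
  expect_false(identical(d2$x1, d$x1) && identical(d2$x2, d$x2))
  # no centers
  d0 <- build_bbd(f, center_runs = 0)
  expect_equal(nrow(d0), 12L)
  expect_false(any(rowSums(d0[, c("x1", "x2", "x3")] == 0) == 3))
  expect_error(build_bbd(f[1:2]), "exactly 3")
})

test_that("reduced models reproduce the published coded coefficients", {
  co1 <- ref_fits$drug_content$coefficients
  expect_equal(unname(round(co1, 2)),
               c(94.11, -0.50, -0.91, 0.80, -2.37, 0.42))
  co2 <- ref_fits$cu$coefficients
  expect_equal(unname(round(co2, 2)),
               c(5.20, 1.06, -0.07, -0.60, 1.13, -3.13))
  # on the orthogonal design the intercept is the response mean
  expect_equal(unname(co1[1]), mean(fx$runs$drug_content), tolerance = 1e-12)
  expect_equal(unname(co2[1]), mean(fx$runs$cu), tolerance = 1e-12)
})

test_that("degenerate fits behave: constant response and aliased terms", {
  runs <- fx$runs
  runs$flat <- 5
  f0 <- fit_rsm(runs, "flat", terms = c("x1", "x2", "x3"))
  expect_equal(unname(f0$coefficients), c(5, 0, 0, 0), tolerance = 1e-12)
  runs$dup <- runs$drug_content
  expect_error(fit_rsm(runs, "dup", terms = c("x1", "x1")), "aliased")
})

test_that("ANOVA reproduces the drug-content table and the R-squared family", {
  a <- anova_rsm(ref_fits$drug_content)
  expect_equal(a$ss_model, 36.88, tolerance = 0.005)
  expect_equal(a$ss_residual, 0.64, tolerance = 0.005)
  expect_equal(a$ss_total, 37.52, tolerance = 0.005)
  expect_equal(a$ss_model + a$ss_residual, a$ss_total, tolerance = 1e-9)
  expect_equal(a$F, 103.25, tolerance = 0.005)
  # F computed from the regression identity R2 agrees with the SS ratio
  F_alt <- (a$r_squared / a$df_model) /
    ((1 - a$r_squared) / a$df_residual)
  expect_equal(a$F, F_alt, tolerance = 1e-9)
  expect_equal(round(a$r_squared, 4), 0.9829)
  expect_equal(round(a$adj_r_squared, 4), 0.9733)
  expect_equal(round(a$pred_r_squared, 4), 0.9274)
  # noiseless synthetic data fits perfectly
  runs <- synth_doe(c(intercept = 10, x1 = 2, x1x2 = -1), noise_sd = 0)
  ap <- anova_rsm(fit_rsm(runs, "y", terms = c("x1", "x1x2")))
  expect_equal(ap$r_squared, 1, tolerance = 1e-12)
  expect_equal(ap$ss_residual, 0, tolerance = 1e-12)
})

test_that("main effects and interactions are orthogonal on the design", {
  coded <- code_factors(fx$runs[, c("filling_level", "rotational_speed",
                                    "blending_time")], blending_factors())
  X <- cbind(coded$x1, coded$x2, coded$x3, coded$x1 * coded$x2,
             coded$x1 * coded$x3, coded$x2 * coded$x3)
  G <- crossprod(X)
  expect_equal(G - diag(diag(G)), matrix(0, 6, 6), tolerance = 1e-12)
})

test_that("predictions match the optimal-setting table", {
  nd <- data.frame(filling_level = 32, rotational_speed = 24,
                   blending_time = 24)
  expect_equal(round(predict(ref_fits$drug_content, nd), 2), 96.67)
  expect_equal(round(predict(ref_fits$cu, nd), 2), 0.07)
  # centre point returns the intercept
  ctr <- data.frame(filling_level = 50, rotational_speed = 20,
                    blending_time = 16.5)
  expect_equal(predict(ref_fits$drug_content, ctr),
               unname(ref_fits$drug_content$coefficients[1]))
  ci <- predict(ref_fits$drug_content, nd, interval = "confidence")
  expect_true(ci$lwr < ci$fit && ci$fit < ci$upr)
})

test_that("coefficients are recovered unbiased from noisy synthetic designs", {
  truth <- c(intercept = 94, x1 = -0.5, x2 = -0.9, x3 = 0.8, x1x2 = -2.4)
  # noiseless: exact recovery
  r0 <- synth_doe(truth, noise_sd = 0, seed = 5)
  f0 <- fit_rsm(r0, "y", terms = c("x1", "x2", "x3", "x1x2"))
  expect_equal(unname(f0$coefficients), unname(truth), tolerance = 1e-9)
  # Monte Carlo: bias ~ 0 and empirical SE matches the OLS formula
  sims <- t(vapply(1:200, function(s) {
    r <- synth_doe(truth, noise_sd = 0.25, seed = 1000 + s)
    fit_rsm(r, "y", terms = c("x1", "x2", "x3", "x1x2"))$coefficients
  }, numeric(5)))
  bias <- colMeans(sims) - truth
  expect_lt(max(abs(bias)), 0.02)
  # SE of a main effect on this design: sigma / sqrt(8)
  expect_equal(sd(sims[, "x1"]), 0.25 / sqrt(8), tolerance = 0.12)
})

test_that("design space and optimisation honour the specification limits", {
  grid <- list(filling_level = seq(30, 70, 2),
               rotational_speed = seq(15, 25, 1))
  pin <- list(blending_time = 24)
  ds <- design_space(ref_fits, ref_specs, grid = grid, fixed = pin)
  expect_true(any(ds$acceptable))
  expect_true(ds$acceptable[ds$filling_level == 32 &
                            ds$rotational_speed == 24])
  # vacuous specs accept everything; impossible specs accept nothing
  all_ok <- design_space(ref_fits,
                         list(drug_content = spec_limits(),
                              cu = spec_limits()), grid = grid, fixed = pin)
  expect_true(all(all_ok$acceptable))
  none <- design_space(ref_fits,
                       list(drug_content = spec_limits(lower = 200)),
                       grid = grid, fixed = pin)
  expect_false(any(none$acceptable))
  # optimisation ranks feasible cells and includes the published optimum
  opt <- optimize_settings(ref_fits, ref_specs, grid = grid, fixed = pin)
  expect_true(any(opt$filling_level == 32 & opt$rotational_speed == 24))
  empty <- optimize_settings(ref_fits,
                             list(drug_content = spec_limits(lower = 200)),
                             grid = grid, fixed = pin)
  expect_equal(nrow(empty), 0L)
})

test_that("backward elimination drops the insignificant speed main effect", {
  f <- fit_rsm(fx$runs, "cu", terms = c("x1", "x2", "x3", "x1x3", "x2x3"),
               backward_alpha = 0.05)
  expect_setequal(f$terms, c("x1", "x3", "x1x3", "x2x3"))
  a <- anova_rsm(f)
  expect_equal(a$ss_model, 56.16, tolerance = 0.005)
  expect_equal(a$F, 59.50, tolerance = 0.005)
})

test_that("run tables round-trip through CSV", {
  path <- tempfile(fileext = ".csv")
  write_runs(fx$runs, path)
  back <- read_runs(path, factors = blending_factors())
  expect_equal(back$drug_content, fx$runs$drug_content)
  f <- fit_rsm(back, "drug_content", terms = c("x1", "x2", "x3"))
  expect_s3_class(f, "rsm_fit")
})
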