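test_that("flow-energy integral matches closed forms", {
  rig <- rheometer_rig()
  # zero trace
  z <- data.frame(h = seq(0, 0.02, length.out = 11), torque = 0, force = 0)
  expect_equal(bfe_energy(z, rig), 0)
  # constant torque and force over depth H: (T/(R tan a) + F) * H
  H <- 0.03
  tr <- data.frame(h = seq(0, H, length.out = 31), torque = 2e-3,
                   force = 0.5)
  al <- abs(rig$helix_angle_deg) * pi / 180
  expect_equal(bfe_energy(tr, rig),
               (2e-3 / (rig$blade_radius * tan(al)) + 0.5) * H,
               tolerance = 1e-12)
  # linear ramp: trapezoid is exact for a linear integrand
  ramp <- data.frame(h = seq(0, H, length.out = 101),
                     torque = seq(0, 4e-3, length.out = 101),
                     force = seq(0, 1, length.out = 101))
  exact <- (4e-3 / (rig$blade_radius * tan(al)) + 1) * H / 2
  expect_equal(bfe_energy(ramp, rig), exact, tolerance = 1e-6 * exact)
  # linearity: scaling the trace scales the energy
  ramp2 <- transform(ramp, torque = 3 * torque, force = 3 * force)
  expect_equal(bfe_energy(ramp2, rig), 3 * bfe_energy(ramp, rig),
               tolerance = 1e-12)
  # zero helix angle is rejected
  expect_error(bfe_energy(tr, rheometer_rig(helix_angle_deg = 0)), "helix")
  expect_error(bfe_energy(data.frame(h = c(0, 2, 1), torque = 0, force = 0),
                          rig), "monotone")
})

test_that("heap-angle estimator is rotation invariant and reads a cone", {
  # synthetic conical cloud with a 25-degree surface
  set.seed(8)
  n <- 2500
  rad <- sqrt(runif(n)) * 0.05
  th <- runif(n, 0, 2 * pi)
  height <- (0.05 - rad) * tan(25 * pi / 180) * runif(n)
  x <- cbind(rad * cos(th), rad * sin(th), height)
  r <- rep(5e-4, n)
  a0 <- heap_angle(x, r)
  expect_equal(a0, 25, tolerance = 3)
  # rotate the cloud 90 degrees about the gravity axis
  xr <- cbind(-x[, 2], x[, 1], x[, 3])
  expect_equal(heap_angle(xr, r), a0, tolerance = 0.5)
})

test_that("surface-angle estimator reads an inclined plane", {
  set.seed(9)
  n <- 1500
  xs <- runif(n, -0.04, 0.04); ys <- runif(n, -0.01, 0.01)
  zs <- -xs * tan(30 * pi / 180) - runif(n, 0, 0.02)
  sa <- surface_angle(cbind(xs, ys, zs), rep(4e-4, n), drum_radius = 0.05)
  expect_equal(sa$angle, 30, tolerance = 3)
  expect_gt(sa$r_squared, 0.8)
})

test_that("static repose angle responds to friction and is seed-stable", {
  dm <- desk_materials()
  base <- dm$desk_powder
  # near-frictionless materials collapse to a flat spread
  slick <- base
  slick$mu_s_pp <- slick$mu_s_pw <- 0.01
  slick$mu_r_pp <- slick$mu_r_pw <- 0
  slick$e_pp <- slick$e_pw <- 0.9
  expect_warning(a_slick <- simulate_static_aor(slick, n_particles = 400,
                                                seed = 2),
                 "frictionless")
  expect_lt(a_slick$angle, 5)
  # rolling-friction ladder at a fixed seed raises the heap
  lo <- base; lo$mu_r_pp <- lo$mu_r_pw <- 0.05
  hi <- base; hi$mu_r_pp <- hi$mu_r_pw <- 0.35
  a_lo <- suppressWarnings(
    simulate_static_aor(lo, n_particles = 400, seed = 2)$angle)
  a_hi <- simulate_static_aor(hi, n_particles = 400, seed = 2)$angle
  expect_gt(a_hi, a_lo)
  # determinism
  again <- simulate_static_aor(hi, n_particles = 400, seed = 2)$angle
  expect_identical(a_hi, again)
})

test_that("calibration loop converges, logs its trail, and flags failure", {
  # cheap analytic stand-in response surface exercises the loop logic
  fake <- function(mat) 12 + 30 * mat$mu_s_pp + 25 * mat$mu_r_pp
  dm <- desk_materials()
  truth <- dm$desk_powder                      # mu_s 0.5, mu_r 0.3
  target <- fake(truth)
  start <- truth
  start$mu_s_pp <- start$mu_s_pw <- 0.2
  start$mu_r_pp <- start$mu_r_pw <- 0.05
  tg <- calibration_target(data.frame(test = "aor",
                                      experimental_value = target))
  out <- calibrate(start, tg, simulators = list(aor = fake), budget = 40)
  expect_true(out$converged)
  expect_lte(out$worst_bias, 0.10)
  expect_equal(fake(out$material), target, tolerance = 0.1 * target)
  # audit trail: worst bias never increases along accepted evaluations
  acc <- out$trail[out$trail$accepted, ]
  expect_true(all(diff(acc$worst_bias) <= 1e-9))
  # already-met targets need no further simulations
  done <- calibrate(truth, tg, simulators = list(aor = fake), budget = 40)
  expect_true(done$converged)
  expect_equal(done$n_evals, 1L)
  # unreachable target exhausts the budget with the flag down
  impossible <- calibration_target(data.frame(test = "aor",
                                              experimental_value = 1e6))
  bad <- calibrate(start, impossible, simulators = list(aor = fake),
                   budget = 10)
  expect_false(bad$converged)
})

test_that("targets CSV reader filters by material", {
  path <- system.file("extdata", "bfe_targets.csv",
                      package = "blendsim")
  tg <- read_calibration_targets(path, material = "st_mg")
  expect_equal(nrow(tg$targets), 1L)
  expect_equal(tg$targets$experimental_value, 16.7)
  expect_equal(tg$tolerance, 0.10)
})
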