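test_that("Hertz normal force follows the 3/2 power law", {
  expect_equal(hertz_normal_force(0, 1e7, 5e-4), 0)
  expect_equal(hertz_normal_force(-1e-6, 1e7, 5e-4), 0)
  d <- 1e-6
  expect_equal(hertz_normal_force(2 * d, 1e7, 5e-4) /
                 hertz_normal_force(d, 1e7, 5e-4), 2^1.5)
  # hand evaluation of (4/3) E* sqrt(R*) dn^1.5
  expect_equal(hertz_normal_force(1e-6, 1e7, 5e-4),
               (4 / 3) * 1e7 * sqrt(5e-4) * (1e-6)^1.5)
})

test_that("equivalent contact properties combine harmonically", {
  m <- test_material(G = 1e7, nu = 0.25)
  eq <- equivalent_props(m, m, radius_a = 1e-3, radius_b = 1e-3)
  E <- 2 * 1e7 * 1.25
  expect_equal(eq$Estar, 1 / (2 * (1 - 0.25^2) / E))
  expect_equal(eq$Rstar, 5e-4)
  mass <- 1000 * (4 / 3) * pi * (1e-3)^3
  expect_equal(eq$mstar, mass / 2)
  # wall contact: infinite partner mass and radius
  eqw <- equivalent_props(m, NULL, radius_a = 1e-3)
  expect_equal(eqw$Rstar, 1e-3)
  expect_equal(eqw$mstar, mass)
  # stiffnesses at a given overlap
  eqo <- equivalent_props(m, m, 1e-3, 1e-3, overlap = 1e-6)
  expect_equal(eqo$Sn, 2 * eq$Estar * sqrt(eq$Rstar * 1e-6))
  expect_equal(eqo$St, 8 * eq$Gstar * sqrt(eq$Rstar * 1e-6))
  expect_error(equivalent_props(m, m, -1, 1), "positive")
})

test_that("damping vanishes for elastic contacts and at zero velocity", {
  expect_equal(damping_ratio(1), 0)
  expect_true(all(damping_ratio(c(0.2, 0.5, 0.9)) > 0))
  expect_true(all(damping_ratio(c(0.01, 0.99)) < 1))
  expect_equal(normal_damping_force(0, 100, 1e-6, 0.5), 0)
  expect_equal(normal_damping_force(0.3, 100, 1e-6, 0), 0)
  # opposes the relative velocity
  expect_lt(normal_damping_force(0.3, 100, 1e-6, 1), 0)
})

test_that("tangential force is capped on the Coulomb cone", {
  z <- tangential_force(1e4, c(0, 0, 0), 0.2, 1e-6, c(0, 0, 0), 0.5, 1)
  expect_equal(z$force, c(0, 0, 0))
  # large spring stretch saturates exactly at mu_s |Fn|
  big <- tangential_force(1e4, c(1, 0, 0), 0, 1e-6, c(0, 0, 0), 0.5, 2)
  expect_equal(sqrt(sum(big$force^2)), 0.5 * 2)
  # the rescaled displacement sits on the cone
  expect_equal(-1e4 * big$delta_t, big$force)
})

test_that("rolling torque opposes spin with magnitude mu_r Fn Rp", {
  expect_equal(rolling_torque(0.3, 1, 1e-3, c(0, 0, 0)), c(0, 0, 0))
  expect_equal(rolling_torque(0, 1, 1e-3, c(5, 0, 0)), c(0, 0, 0))
  tq <- rolling_torque(0.3, 2, 1e-3, c(0, 0, 10))
  expect_equal(tq, c(0, 0, -0.3 * 2 * 1e-3))
})

test_that("JKR force reduces to Hertz and detaches at 3 pi gamma R*", {
  Est <- 2.4e7; Rst <- 5e-4; gam <- 0.02
  expect_equal(jkr_normal_force(0, gam, Est, Rst), 0)
  d <- 1e-6
  expect_equal(jkr_normal_force(sqrt(Rst * d), 0, Est, Rst),
               hertz_normal_force(d, Est, Rst))
  # pull-off magnitude: fine-grid minimisation against the closed form
  a <- seq(1e-8, 5e-4, length.out = 100000)
  expect_equal(-min(jkr_normal_force(a, gam, Est, Rst)),
               jkr_pulloff_force(gam, Rst), tolerance = 1e-3)
  # overlap-radius relation round-trips through the Newton solve
  aa <- jkr_contact_radius(d, gam, Est, Rst)
  expect_equal(aa^2 / Rst - sqrt(4 * pi * gam * aa / Est), d,
               tolerance = 1e-9 * d)
  # past the detachment overlap there is no neck
  expect_true(is.na(jkr_contact_radius(-1e-3, gam, Est, Rst)))
  expect_equal(jkr_contact_radius(d, 0, Est, Rst), sqrt(Rst * d))
})

test_that("Rayleigh time step scales linearly with the smallest radius", {
  dt1 <- rayleigh_timestep(1e-3, 1000, 1e7, 0.25, 0.25)
  dt2 <- rayleigh_timestep(c(1e-3, 5e-4), c(1000, 1000), c(1e7, 1e7),
                           c(0.25, 0.25), 0.25)
  expect_equal(dt2, dt1 / 2)
  # hand evaluation for the lubricant material at the default 100x upscale
  stmg <- fx$materials$st_mg
  r <- stmg$d10 * 100 * 1e-6 / 2
  expect_equal(
    rayleigh_timestep(r, stmg$true_density * 1000, stmg$shear_modulus,
                      stmg$poisson, 0.25),
    0.25 * pi * r * sqrt(stmg$true_density * 1000 / stmg$shear_modulus) /
      (0.1631 * stmg$poisson + 0.8766))
  expect_error(rayleigh_timestep(1e-3, 1000, 1e7, 0.25, 0), "positive")
})
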