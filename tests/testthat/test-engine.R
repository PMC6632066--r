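test_that("a free particle follows the closed-form ballistic trajectory", {
  m <- test_material()
  sys <- particle_system(matrix(c(0, 0, 1), 1, 3), 1e-3, 1, list(t = m))
  res <- dem_run(sys, duration = 0.1, dt = 1e-5)
  expect_equal(res$final$x[3], 1 - 0.5 * 9.81 * 0.1^2, tolerance = 1e-4)
})

test_that("elastic head-on collision conserves momentum and energy", {
  sys <- two_sphere_impact(test_material(e = 1))
  res <- dem_run(sys, duration = 2e-4, dt = system_timestep(sys, 0.1))
  p <- colSums(res$final$v * sys$mass)
  expect_equal(p, c(0, 0, 0), tolerance = 1e-12 * sum(sys$mass))
  ke0 <- 0.5 * sum(sys$mass * rowSums(sys$v^2))
  ke1 <- 0.5 * sum(sys$mass * rowSums(res$final$v^2))
  expect_lt(abs(ke1 - ke0) / ke0, 0.005)
  expect_lte(ke1, ke0 * (1 + 1e-6))   # no energy creation
})

test_that("damped impacts rebound at the configured restitution", {
  sys <- two_sphere_impact(test_material(e = 0.5))
  # independent oracle: integrate the single-contact ODE with a fine
  # Runge-Kutta step (midpoint), far below the engine's dt
  mat <- test_material(e = 0.5)
  eq <- equivalent_props(mat, mat, 1e-3, 1e-3)
  beta <- damping_ratio(0.5)
  f <- function(delta, v) {
    fe <- hertz_normal_force(delta, eq$Estar, eq$Rstar)
    Sn <- 2 * eq$Estar * sqrt(eq$Rstar * max(delta, 0))
    fd <- -2 * sqrt(5 / 6) * beta * sqrt(Sn * eq$mstar) * v
    (fe + fd) / eq$mstar
  }
  # delta' = -v_rel_closing; integrate until separation
  h <- 1e-9; delta <- 0; v <- -1   # closing speed 1 m/s
  repeat {
    a1 <- f(delta, v)
    vm <- v + a1 * h / 2; dm <- delta - (v + vm) / 2 * h / 2
    a2 <- f(max(dm, 0), vm)
    v <- v + a2 * h; delta <- delta - v * h
    if (delta <= 0 && v > 0) break
  }
  e_oracle <- v / 1
  res <- dem_run(sys, duration = 2e-4, dt = system_timestep(sys, 0.1))
  e_engine <- abs(res$final$v[1, 1] - res$final$v[2, 1])
  expect_equal(e_oracle, 0.5, tolerance = 0.02)
  expect_equal(e_engine, 0.5, tolerance = 0.02)
})

test_that("a dropped sphere rebounds to e-squared of its drop height", {
  m <- test_material(e = 0.5)
  plate <- wall(mesh_plate(0.05, 0, n = 24))
  h0 <- 0.02
  sys <- particle_system(matrix(c(0.003, 0.001, h0 + 1e-3), 1, 3), 1e-3, 1,
                         list(t = m))
  res <- dem_run(sys, list(plate), duration = 0.25, save_interval = 0.002,
                 dt = 2e-6)
  zs <- vapply(res$X, function(x) x[3], numeric(1))
  vz <- vapply(res$V, function(v) v[3], numeric(1))
  first_up <- which(diff(sign(vz)) > 0)[1]
  peak <- max(zs[first_up:length(zs)]) - 1e-3
  expect_lt(abs(peak / h0 - 0.25), 0.02)
})

test_that("grid neighbour search equals brute force on random scenes", {
  for (s in 1:20) {
    set.seed(s)
    n <- 100
    X <- matrix(runif(3 * n, 0, 1), n, 3)
    cutoff <- runif(1, 0.08, 0.25)
    got <- neighbor_search(X, cutoff)
    d <- as.matrix(dist(X))
    bf <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    bf <- bf[order(bf[, 1], bf[, 2]), , drop = FALSE]
    expect_equal(unname(got[order(got[, 1], got[, 2]), , drop = FALSE]),
                 unname(cbind(bf[, 1], bf[, 2])))
  }
  # degenerate coincident points are reported once
  P <- rbind(c(0, 0, 0), c(0, 0, 0))
  expect_equal(nrow(neighbor_search(P, 0.1)), 1L)
  # distant particles yield nothing
  expect_equal(nrow(neighbor_search(rbind(c(0, 0, 0), c(10, 0, 0)), 1)), 0L)
})

test_that("wall contact handles plane, miss, wedge and degenerate faces", {
  plate <- wall(mesh_plate(1, 0, n = 16))
  wc <- wall_contact(c(0.1, 0.05, 0.08), 0.1, plate)
  expect_equal(length(wc$overlap), 1L)
  expect_equal(wc$overlap, 0.02, tolerance = 1e-12)
  expect_equal(drop(wc$normal), c(0, 0, 1), tolerance = 1e-9)
  # outside the mesh: no contact
  far <- wall_contact(c(5, 5, 5), 0.1, plate)
  expect_equal(length(far$overlap), 0L)
  # sphere resting in a 90-degree wedge: two contacts, net force along the
  # bisector (static balance oracle)
  wedge <- blendsim:::tri_mesh(
    rbind(c(-1, -1, 0), c(1, -1, 0), c(1, 1, 0), c(-1, 1, 0),
          c(-1, -1, 2), c(-1, 1, 2)),
    rbind(c(1, 2, 3), c(1, 3, 4), c(1, 5, 6), c(1, 6, 4)))
  wc2 <- wall_contact(c(-0.92, 0, 0.08), 0.1, wall(wedge))
  expect_equal(length(wc2$overlap), 2L)
  net <- colSums(wc2$normal * hertz_normal_force(wc2$overlap, 1e7, 0.1))
  expect_equal(net[2], 0, tolerance = 1e-9)
  expect_true(net[1] > 0 && net[3] > 0)
  # degenerate triangle is skipped with a warning
  degen <- blendsim:::tri_mesh(rbind(c(-1, -1, 0), c(1, -1, 0), c(1, 1, 0),
                                     c(0, 0, 0)),
                               rbind(c(1, 2, 3), c(4, 4, 4)))
  expect_warning(wall_contact(c(0, -0.5, 0.05), 0.1, wall(degen)),
                 "degenerate")
})

test_that("rotating walls impose the rigid-body surface velocity", {
  drum <- mesh_drum(0.2, 0.1, n = 48)
  w <- wall(drum, axis_point = c(0, 0, 0), axis_dir = c(0, 1, 0), rpm = 24)
  # sphere just touching the shell at the bottom
  wc <- wall_contact(c(0, 0, -0.2 + 0.009), 0.01, w, t = 0)
  expect_gte(length(wc$overlap), 1L)
  omega <- 24 * 2 * pi / 60
  v_expect <- omega * sqrt(sum(wc$point[1, c(1, 3)]^2))
  expect_equal(sqrt(sum(wc$wall_velocity[1, ]^2)), v_expect,
               tolerance = 1e-9)
})

test_that("cohesionless JKR reproduces the Hertz trajectory exactly", {
  m_h <- test_material(e = 0.8)
  m_j <- test_material(e = 0.8, gamma = 0)
  a <- dem_run(two_sphere_impact(m_h), duration = 1e-4,
               dt = system_timestep(two_sphere_impact(m_h), 0.1))
  b <- dem_run(two_sphere_impact(m_j), duration = 1e-4,
               dt = system_timestep(two_sphere_impact(m_j), 0.1))
  expect_identical(a$final$x, b$final$x)
})

test_that("cohesive contacts slow separation relative to Hertz", {
  m_j <- test_material(e = 1, gamma = 0.05)
  m_h <- test_material(e = 1)
  sys_j <- two_sphere_impact(m_j, speed = 0.05)
  sys_h <- two_sphere_impact(m_h, speed = 0.05)
  dt <- system_timestep(sys_j, 0.1)
  rj <- dem_run(sys_j, duration = 4e-4, dt = dt)
  rh <- dem_run(sys_h, duration = 4e-4, dt = dt)
  v_j <- abs(rj$final$v[1, 1] - rj$final$v[2, 1])
  v_h <- abs(rh$final$v[1, 1] - rh$final$v[2, 1])
  expect_lt(v_j, v_h)   # adhesion dissipates separation energy
})

test_that("spinning sphere on a plane decays at the rolling-friction rate", {
  m <- test_material(e = 0.5, mu_s = 0.5, mu_r = 0.3)
  plate <- wall(mesh_plate(0.05, 0, n = 24))
  r <- 1e-3
  sys <- particle_system(matrix(c(0, 0, r * 0.9995), 1, 3), r, 1,
                         list(t = m), w = matrix(c(0, 0, 40), 1, 3))
  res <- dem_run(sys, list(plate), duration = 0.04, save_interval = 0.002,
                 dt = 2e-6)
  wz <- vapply(res$W, function(w) w[3], numeric(1))
  # torque = mu_r * m g * r about z; I = 2/5 m r^2 -> linear decay rate
  mass <- unname(sys$mass[1])
  rate <- 0.3 * mass * 9.81 * r / (0.4 * mass * r^2)
  # constant-torque decay: compare the slope over the first interval,
  # before the sphere stops (full stop takes 40/rate ~ 5.4 ms)
  dec <- (wz[1] - wz[2]) / 0.002
  expect_equal(dec, rate, tolerance = 0.05)
  expect_lt(wz[length(wz)], 1)   # spun down
})

test_that("momentum is conserved in a closed gravity-free cluster", {
  set.seed(3)
  # non-overlapping jittered lattice so the cluster starts with zero
  # stored elastic energy
  g <- as.matrix(expand.grid(x = (0:3) * 1.3e-3, y = (0:3) * 1.3e-3,
                             z = (0:2) * 1.3e-3))
  n <- nrow(g)
  m <- test_material(e = 0.7, mu_s = 0.4, mu_r = 0.1)
  X <- g + matrix(runif(3 * n, -1e-4, 1e-4), n, 3)
  V <- matrix(rnorm(3 * n, 0, 0.2), n, 3)
  sys <- particle_system(X, rep(5e-4, n), rep(1L, n), list(t = m), v = V,
                         gravity = c(0, 0, 0))
  res <- dem_run(sys, duration = 5e-3, dt = system_timestep(sys, 0.1),
                 integrator = "verlet")
  p0 <- colSums(sys$v * sys$mass)
  p1 <- colSums(res$final$v * res$final$mass)
  expect_equal(p1, p0, tolerance = 1e-10)
  ke0 <- 0.5 * sum(sys$mass * rowSums(sys$v^2))
  ke1 <- 0.5 * sum(res$final$mass * rowSums(res$final$v^2))
  expect_lte(ke1, ke0 * (1 + 1e-4))   # dissipative contacts only
})

test_that("identical inputs give identical trajectories", {
  sc <- mini_scene("two_body", seed = 4)
  a <- dem_run(sc$system, duration = 1e-3,
               dt = system_timestep(sc$system, 0.2))
  b <- dem_run(sc$system, duration = 1e-3,
               dt = system_timestep(sc$system, 0.2))
  expect_identical(a$final$x, b$final$x)
  expect_identical(a$final$v, b$final$v)
})
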