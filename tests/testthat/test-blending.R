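test_that("Carr index follows the density ratio", {
  expect_equal(carr_index(0.25, 0.25), 0)
  expect_equal(carr_index(0.8, 1.0), 20)
  expect_equal(carr_index(0.20, 0.25), 20)
  expect_error(carr_index(0.3, 0.25), "exceed")
  expect_error(carr_index(-1, 1), "positive")
})

test_that("formulations validate and expose the nominal API fraction", {
  f <- amlodipine_formulation()
  expect_equal(sum(f$components), 1, tolerance = 1e-12)
  expect_equal(f$nominal_api_fraction, 0.06935)
  expect_error(formulation(c(a = 0.5, b = 0.4), "a"), "sum to 1")
  expect_error(formulation(c(a = 0.5, b = 0.5), "c"), "api")
})

test_that("content uniformity is the percent RSD of bin contents", {
  expect_equal(content_uniformity(c(100, 100, 100)), 0)
  expect_equal(content_uniformity(c(90, 110)), 100 * sqrt(200) / 100)
  cts <- c(91, 97, 104, 99)
  expect_equal(content_uniformity(3 * cts), content_uniformity(cts))
  expect_true(is.na(content_uniformity(c(0, 0))))
  expect_error(content_uniformity(100), "two bins")
})

test_that("bin sampling normalises drug content against the recipe", {
  # idealised two-material system: API fraction exactly nominal in bin 1,
  # zero in bin 2
  form <- formulation(c(api = 0.1, bulk = 0.9), "api")
  mats <- list(api = test_material(), bulk = test_material())
  names(mats) <- c("api", "bulk")
  # masses equal: choose radii equal, same density
  x <- rbind(c(0, 0, 0), c(0.001, 0, 0),          # bin 1: 1 API + 9 bulk
             matrix(c(rep(0.0005, 8), rep(0, 8), seq_len(8) * 0.001),
                    8, 3))
  x <- rbind(x, sweep(x, 2, c(1, 0, 0), "+"))     # bin 2: copy, no API
  mat_id <- c(1L, rep(2L, 9L), rep(2L, 10L))
  sys <- particle_system(x, rep(5e-4, 20), mat_id, mats,
                         gravity = c(0, 0, 0))
  bins <- data.frame(cx = c(0, 1), cy = 0, cz = 0.0045, radius = 0.05,
                     height = 0.05)
  sb <- sample_bins(sys$x, sys, bins, form, min_bins = 2)
  expect_equal(sb$drug_content[1], (1 / 10) / 0.1 * 100)   # exactly 100%
  expect_equal(sb$drug_content[2], 0)
  # metrics invariant under rigid rotation of snapshot + bins
  rot <- function(p) cbind(-p[, 2], p[, 1], p[, 3])
  bins_r <- bins
  bins_r$cx <- -c(0, 0); bins_r$cy <- c(0, 1)
  sb_r <- sample_bins(rot(sys$x), sys, bins_r, form, min_bins = 2)
  expect_equal(sb_r$drug_content, sb$drug_content)
})

test_that("well-mixed sampling approaches the binomial floor", {
  set.seed(21)
  form <- formulation(c(api = 0.1, bulk = 0.9), "api")
  mats <- list(api = test_material(), bulk = test_material())
  n <- 4000
  x <- matrix(runif(3 * n, 0, 0.1), n, 3)
  mat_id <- ifelse(runif(n) < 0.1, 1L, 2L)
  sys <- particle_system(x, rep(5e-4, n), mat_id, mats,
                         gravity = c(0, 0, 0))
  bins <- sampling_bins(x)
  sb <- sample_bins(x, sys, bins, form)
  cu <- content_uniformity(sb$drug_content)
  # binomial floor: RSD ~ sqrt((1-p)/(n_bin p)); allow generous MC slack
  nb <- mean(sb$n)
  floor_cu <- 100 * sqrt((1 - 0.1) / (nb * 0.1))
  expect_lt(cu, 3 * floor_cu)
  expect_gt(cu, floor_cu / 3)
})

test_that("regression comparison reports the standard summary", {
  a <- c(90, 92, 95, 97, 99)
  id <- compare_series(a, a)
  expect_equal(id$slope, 1, tolerance = 1e-12)
  expect_equal(id$intercept, 0, tolerance = 1e-9)
  expect_equal(id$r_squared, 1, tolerance = 1e-12)
  ln <- compare_series(a, 2 * a + 1)
  expect_equal(ln$slope, 2, tolerance = 1e-12)
  expect_equal(ln$intercept, 1, tolerance = 1e-9)
  # drop-first trims initial high-variability points
  d <- compare_series(c(0, a), c(50, 2 * a + 1), drop_first = 1)
  expect_equal(d$slope, 2, tolerance = 1e-12)
  expect_error(compare_series(rep(1, 5), a), "zero variance")
  expect_error(compare_series(a[1:2], a[1:2]), "three")
  # noisy series: R2 close to the analytic signal fraction
  set.seed(5)
  sim <- seq(80, 100, length.out = 40)
  noise_sd <- 2
  exp_v <- sim + rnorm(40, 0, noise_sd)
  cs <- compare_series(sim, exp_v)
  r2_true <- var(sim) / (var(sim) + noise_sd^2)
  expect_equal(cs$r_squared, r2_true, tolerance = 0.08)
  expect_equal(cs$s, noise_sd, tolerance = 0.5)
})

test_that("pre-mixed ideal snapshots meet specification at the first index", {
  # fabricate snapshots where each vertical column holds exactly one API
  # particle in ten, and bins that span full columns: every bin then reads
  # exactly 100% content and CU 0
  form <- formulation(c(api = 0.1, bulk = 0.9), "api")
  mats <- list(api = test_material(), bulk = test_material())
  g <- as.matrix(expand.grid(x = seq(0, 0.09, 0.01),
                             y = seq(0, 0.09, 0.01),
                             z = seq(0, 0.09, 0.01)))
  mat_id <- ifelse(abs(g[, 3] - 0.05) < 1e-9, 1L, 2L)   # one z-layer is API
  sys <- particle_system(g, rep(5e-4, nrow(g)), mat_id, mats,
                         gravity = c(0, 0, 0))
  bins <- expand.grid(cx = c(0.01, 0.035, 0.06, 0.085),
                      cy = c(0.025, 0.065), cz = 0.045)
  bins <- data.frame(bins, radius = 0.012, height = 0.5)
  fake <- structure(list(times = c(1, 2), X = list(g, g)),
                    class = "dem_result")
  ti <- t_index_series(fake, sys, form, interval = 1, bins = bins)
  expect_true(ti$metrics$meets_spec[1])
  expect_equal(ti$t_index_met, 1L)
  # fully segregated, static: specs never met, reported as not reached
  seg_id <- ifelse(g[, 1] < 0.045, 1L, 2L)
  sys_seg <- particle_system(g, rep(5e-4, nrow(g)), seg_id, mats,
                             gravity = c(0, 0, 0))
  ti_seg <- t_index_series(fake, sys_seg, form, interval = 1, bins = bins)
  expect_false(any(ti_seg$metrics$meets_spec))
  expect_true(is.na(ti_seg$t_index_met))
})

test_that("blender filling honours recipe, bed volume and layering", {
  sc <- mini_scene("v_blender", budget = 1000, seed = 2, rpm = 24)
  audit <- recipe_audit(sc$system, sc$formulation)
  expect_lt(max(abs(audit$deviation)), 0.01)
  target <- attr(sc$system, "bed_volume_target")
  expect_equal(bed_volume(sc$system), target, tolerance = 0.10)
  # all particles inside the shell after settling
  expect_true(all(sc$blender$mesh$inside(sc$system$x)))
  # zero rotation: after full relaxation the bed stays put
  still <- wall(sc$blender$mesh, axis_point = sc$blender$axis_point,
                axis_dir = sc$blender$axis_dir, rpm = 0)
  relaxed <- blendsim:::.settle(sc$system, list(still), max_time = 3,
                                dt = system_timestep(sc$system, 0.3),
                                ke_rest = 1e-10)
  res <- dem_run(relaxed, list(still), duration = 0.3, dt_fraction = 0.3)
  drift <- sqrt(rowSums((res$final$x - relaxed$x)^2))
  expect_lt(unname(stats::quantile(drift, 0.99)), max(relaxed$radius))
})

test_that("short blending runs conserve particles and report metrics", {
  sc <- mini_scene("v_blender", budget = 700, seed = 5, rpm = 24)
  res <- run_blending(sc$system, sc$blender, duration = 2.5,
                      save_interval = 0.5, dt_fraction = 0.3)
  # one full revolution at 24 rpm takes 2.5 s: wall phase returns home
  expect_equal(res$times[length(res$times)] * sc$blender$omega, 2 * pi,
               tolerance = 0.02)
  expect_true(all(vapply(res$X, nrow, 0L) == nrow(sc$system$x)))
  ti <- t_index_series(res, sc$system, sc$formulation, interval = 0.5,
                       blender = sc$blender)
  expect_equal(nrow(ti$metrics), 5L)
  expect_true(all(is.finite(ti$metrics$cu)))
})
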