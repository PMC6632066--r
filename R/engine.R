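# R-side surface of the DEM engine: particle systems, pair-property tables
# and the run/step drivers over the compiled core.

#' Construct a particle system
#'
#' @param x n x 3 matrix of positions (m).
#' @param radius particle radii (m).
#' @param material integer index into `materials` per particle.
#' @param materials named list of [material_params()].
#' @param v,w optional n x 3 velocities (m/s) and angular velocities
#'   (rad/s); default zero.
#' @param gravity gravity vector (default `c(0, 0, -9.81)` m/s^2).
#' @return object of class `particle_system`.
#' @export
particle_system <- function(x, radius, material, materials,
                            v = NULL, w = NULL,
                            gravity = c(0, 0, -9.81)) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (any(radius <= 0)) stop("radii must be positive", call. = FALSE)
  if (length(radius) != n || length(material) != n)
    stop("x, radius and material must agree in length", call. = FALSE)
  if (is.null(v)) v <- matrix(0, n, 3)
  if (is.null(w)) w <- matrix(0, n, 3)
  if (anyNA(x) || anyNA(v) || anyNA(w))
    stop("state contains NA", call. = FALSE)
  dens <- vapply(materials, function(m) m$true_density * 1000, numeric(1))
  mass <- dens[material] * (4 / 3) * pi * radius^3
  structure(list(x = x, v = as.matrix(v), w = as.matrix(w),
                 radius = radius, material = as.integer(material),
                 materials = materials, mass = mass, gravity = gravity),
            class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat(sprintf("particle_system: %d particles, %d materials, total mass %.3g kg\n",
              nrow(x$x), length(x$materials), sum(x$mass)))
  invisible(x)
}

# (k+1)^2 pair-property matrices (index k+1 = wall) for the compiled core.
.pair_matrices <- function(materials, wall = wall_material()) {
  k <- length(materials)
  E <- G <- B <- MS <- MR <- GA <- matrix(0, k + 1, k + 1)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      eq <- equivalent_props(materials[[i]], materials[[j]],
                             radius_a = 1, radius_b = 1)
      co <- .pair_coefficients(materials[[i]], materials[[j]])
      E[i, j] <- eq$Estar; G[i, j] <- eq$Gstar
      B[i, j] <- damping_ratio(co$e)
      MS[i, j] <- co$mu_s; MR[i, j] <- co$mu_r; GA[i, j] <- co$gamma
    }
    eqw <- equivalent_props(materials[[i]], wall, radius_a = 1,
                            radius_b = Inf)
    cow <- .pair_coefficients(materials[[i]], NULL)
    E[i, k + 1] <- E[k + 1, i] <- eqw$Estar
    G[i, k + 1] <- G[k + 1, i] <- eqw$Gstar
    B[i, k + 1] <- B[k + 1, i] <- damping_ratio(cow$e)
    MS[i, k + 1] <- MS[k + 1, i] <- cow$mu_s
    MR[i, k + 1] <- MR[k + 1, i] <- cow$mu_r
    GA[i, k + 1] <- GA[k + 1, i] <- cow$gamma
  }
  list(Estar = E, Gstar = G, beta = B, mu_s = MS, mu_r = MR, gamma = GA)
}

.wall_for_cpp <- function(w) {
  stopifnot(inherits(w, "wall"))
  list(vertices = w$mesh$vertices, triangles = w$mesh$triangles,
       axis_point = w$axis_point, axis_dir = w$axis_dir,
       omega = w$omega, v_trans = w$v_trans)
}

#' Stable time step for a particle system
#'
#' @param system a [particle_system()].
#' @param fraction fraction of the Rayleigh time.
#' @export
system_timestep <- function(system, fraction = 0.25) {
  mats <- system$materials
  rho <- vapply(mats, function(m) m$true_density * 1000, numeric(1))
  G <- vapply(mats, function(m) m$shear_modulus, numeric(1))
  nu <- vapply(mats, function(m) m$poisson, numeric(1))
  i <- system$material
  rayleigh_timestep(system$radius, rho[i], G[i], nu[i], fraction)
}

#' Run the DEM integrator
#'
#' Advances a particle system for `duration` seconds of simulated time
#' under gravity, particle-particle and particle-wall contact forces,
#' saving snapshots at `save_interval`.  Deterministic: no randomness is
#' consumed.
#'
#' @param system a [particle_system()].
#' @param walls list of [wall()] objects.
#' @param duration simulated time (s).
#' @param save_interval snapshot spacing (s); defaults to `duration`
#'   (final state only).
#' @param dt time step (s); default 25% of the Rayleigh time.
#' @param dt_fraction Rayleigh fraction used when `dt` is `NULL`.
#' @param t0 start time (s); wall motion phases are evaluated at absolute
#'   time, so chained runs continue smoothly.
#' @param domain_radius abort radius for escaped particles (m); defaults
#'   to 100x the system extent.
#' @param integrator `"euler"` (semi-implicit Euler, the default) or
#'   `"verlet"` (velocity Verlet, two force evaluations per step; tighter
#'   energy behaviour for impact studies).
#' @return object of class `dem_result`: `times`, lists `X`, `V`, `W`,
#'   `kinetic_energy`, wall load series (`wall_torque`,
#'   `wall_axial_force`, time-averaged per save interval), and `final`,
#'   the updated `particle_system`.
#' @export
dem_run <- function(system, walls = list(), duration, save_interval = NULL,
                    dt = NULL, dt_fraction = 0.25, t0 = 0,
                    domain_radius = NULL,
                    integrator = c("euler", "verlet")) {
  integrator <- match.arg(integrator)
  stopifnot(inherits(system, "particle_system"))
  if (is.null(dt)) dt <- system_timestep(system, dt_fraction)
  lim <- system_timestep(system, 1)
  if (dt > 0.4 * lim)
    warning(sprintf("dt = %.3g s exceeds 40%% of the Rayleigh time (%.3g s)",
                    dt, lim), call. = FALSE)
  if (is.null(save_interval)) save_interval <- duration
  save_every <- max(1L, as.integer(round(save_interval / dt)))
  nsteps <- max(1L, as.integer(round(duration / (dt * save_every)))) *
    save_every
  if (is.null(domain_radius))
    domain_radius <- 100 * max(sqrt(rowSums(system$x^2)), 1e-3)
  pm <- .pair_matrices(system$materials)
  res <- cpp_dem_run(system$x, system$v, system$w, system$radius,
                     system$material, system$mass,
                     pm$Estar, pm$Gstar, pm$beta, pm$mu_s, pm$mu_r, pm$gamma,
                     lapply(walls, .wall_for_cpp), system$gravity,
                     dt, nsteps, save_every, t0, domain_radius,
                     if (integrator == "verlet") 1L else 0L)
  k <- length(res$times)
  final <- system
  final$x <- res$X[[k]]; final$v <- res$V[[k]]; final$w <- res$W[[k]]
  structure(list(times = res$times, X = res$X, V = res$V, W = res$W,
                 kinetic_energy = res$kinetic_energy,
                 wall_torque = res$wall_torque,
                 wall_axial_force = res$wall_axial_force,
                 dt = dt, final = final),
            class = "dem_result")
}

#' Advance a particle system by a single time step
#'
#' @inheritParams dem_run
#' @param dt time step (s).
#' @return the updated `particle_system`.
#' @export
dem_step <- function(system, walls = list(), dt, t0 = 0) {
  res <- dem_run(system, walls, duration = dt, save_interval = dt, dt = dt,
                 t0 = t0)
  res$final
}

#' Candidate contact pairs by uniform-grid broad phase
#'
#' Returns every unordered particle pair within `cutoff` of each other
#' (center-to-center); a superset of the truly overlapping pairs and
#' identical to the brute-force pair list at the same cutoff.
#'
#' @param system a [particle_system()] (or an n x 3 position matrix).
#' @param cutoff search distance (m); must cover the largest particle
#'   diameter.
#' @return two-column integer matrix of pair indices, `i < j`, sorted.
#' @export
neighbor_search <- function(system, cutoff) {
  x <- if (inherits(system, "particle_system")) system$x else as.matrix(system)
  r <- if (inherits(system, "particle_system")) system$radius else
    rep(0, nrow(x))
  if (length(r) && cutoff < 2 * max(r))
    stop("cutoff must be at least the largest particle diameter",
         call. = FALSE)
  cpp_neighbor_pairs(x, r, cutoff)
}

#' Contacts between one sphere and a moving wall mesh
#'
#' Closest-point contact detection against every triangle within reach,
#' deduplicated per smooth surface patch, with the wall surface velocity at
#' each contact point.
#'
#' @param x sphere centre (length-3).
#' @param r sphere radius (m).
#' @param wall a [wall()].
#' @param t evaluation time (s) for the wall motion.
#' @return list with `point`, `normal` (pointing toward the sphere),
#'   `overlap` and `wall_velocity` (one row per contact).
#' @export
wall_contact <- function(x, r, wall, t = 0) {
  area2 <- function(a, b, c) sqrt(sum(.cross3(b - a, c - a)^2))
  v <- wall$mesh$vertices; tr <- wall$mesh$triangles
  deg <- vapply(seq_len(nrow(tr)), function(i)
    area2(v[tr[i, 1], ], v[tr[i, 2], ], v[tr[i, 3], ]) < 1e-20, logical(1))
  if (any(deg)) {
    warning(sum(deg), " degenerate (zero-area) triangle(s) skipped",
            call. = FALSE)
    wall$mesh$triangles <- tr[!deg, , drop = FALSE]
  }
  cpp_wall_contact(as.numeric(x), r, .wall_for_cpp(wall), t, reach = 0)
}

#' Snapshot a DEM result as a columnar trajectory table
#'
#' @param result a [dem_run()] result.
#' @param system the originating [particle_system()] (for radii and
#'   material names).
#' @return data frame with columns `t, id, material, x, y, z, vx, vy, vz,
#'   radius`.
#' @export
trajectory_table <- function(result, system) {
  mats <- names(system$materials)
  do.call(rbind, lapply(seq_along(result$times), function(k) {
    X <- result$X[[k]]; V <- result$V[[k]]
    data.frame(t = result$times[k], id = seq_len(nrow(X)),
               material = mats[system$material],
               x = X[, 1], y = X[, 2], z = X[, 3],
               vx = V[, 1], vy = V[, 2], vz = V[, 3],
               radius = system$radius)
  }))
}

#' @rdname trajectory_table
#' @param path CSV path.
#' @export
write_trajectory <- function(result, system, path) {
  write.csv(trajectory_table(result, system), path, row.names = FALSE)
  invisible(path)
}

# Draw particle radii from the three-point D10/D50/D90 approximation of the
# size distribution (weights 1/4, 1/2, 1/4), after the material's upscale.
sample_radii <- function(material, n) {
  d <- sample(c(material$d10, material$d50, material$d90), n, replace = TRUE,
              prob = c(0.25, 0.5, 0.25))
  d * material$size_scale * 1e-6 / 2
}
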