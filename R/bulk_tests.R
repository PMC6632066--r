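# Virtual bulk tests used to calibrate interaction coefficients: static
# angle of repose (funnel over plate), dynamic angle of repose (rotating
# drum), and an FT4-style basic-flow-energy test.  Rig sizes scale with the
# particle size so miniature desk fixtures stay inside a test-suite time
# budget; the estimators mirror how the physical tests are read out.

# ---- estimators -------------------------------------------------------------

#' Heap angle from a settled particle cloud
#'
#' Fits a cone to the free surface by radial height regression: particles
#' are binned by radial distance from the heap axis, the surface height of
#' each bin is the top of its highest particle, and a line is fitted to
#' height versus radius.  The outer `trim` fraction of the radial extent is
#' excluded (rim effects), as are bins below the peak shoulder.
#'
#' @param x n x 3 positions of settled particles (m).
#' @param radius particle radii (m).
#' @param z_floor height of the supporting plate (m).
#' @param trim outer radial fraction to exclude (default 0.1).
#' @param nbins radial bins (default 12).
#' @return heap angle in degrees; near 0 for a collapsed monolayer.
#' @export
heap_angle <- function(x, radius, z_floor = 0, trim = 0.1, nbins = 12) {
  keep <- x[, 3] > z_floor - 1e-9
  x <- x[keep, , drop = FALSE]; radius <- radius[keep]
  if (nrow(x) < 3) return(0)
  ctr <- c(mean(x[, 1]), mean(x[, 2]))
  rad <- sqrt((x[, 1] - ctr[1])^2 + (x[, 2] - ctr[2])^2)
  top <- x[, 3] + radius - z_floor
  rmax <- max(rad) * (1 - trim)
  if (rmax <= 0) return(0)
  bins <- cut(rad, seq(0, rmax, length.out = nbins + 1), include.lowest = TRUE)
  h <- tapply(top, bins, max)
  mids <- (seq_len(nbins) - 0.5) * rmax / nbins
  ok <- !is.na(h)
  if (sum(ok) < 3) return(0)
  slope <- coef(lm(h[ok] ~ mids[ok]))[2]
  ang <- atan(-slope) * 180 / pi
  max(ang, 0)
}

#' Free-surface angle in a rotating drum
#'
#' Line fit to the free surface in the axial-mean cross-section: particles
#' are binned along the flow direction (x, the horizontal normal to the
#' drum axis), each bin's surface is its highest particle top, and the
#' angle is the fitted slope.
#'
#' @param x n x 3 positions (m); drum axis along y.
#' @param radius particle radii (m).
#' @param drum_radius drum radius (m) for trimming the end bins.
#' @param nbins surface bins.
#' @return list with `angle` (deg) and `r_squared` of the line fit.
#' @export
surface_angle <- function(x, radius, drum_radius, nbins = 12) {
  lim <- 0.7 * drum_radius
  keep <- abs(x[, 1]) < lim
  xs <- x[keep, 1]; top <- x[keep, 3] + radius[keep]
  bins <- cut(xs, seq(-lim, lim, length.out = nbins + 1),
              include.lowest = TRUE)
  h <- tapply(top, bins, max)
  mids <- seq(-lim, lim, length.out = nbins + 1)
  mids <- (mids[-1] + mids[-(nbins + 1)]) / 2
  ok <- !is.na(h)
  if (sum(ok) < 3) return(list(angle = NA_real_, r_squared = NA_real_))
  fit <- lm(h[ok] ~ mids[ok])
  list(angle = abs(atan(coef(fit)[[2]])) * 180 / pi,
       r_squared = summary(fit)$r.squared)
}

# seeded loose lattice of n particle centres inside a vertical cylinder
# (radius R, between z0 and as high as needed), spacing s
.lattice_cylinder <- function(n, R, z0, s) {
  pts <- NULL
  z <- z0
  while (is.null(pts) || nrow(pts) < n) {
    xy <- expand.grid(x = seq(-R + s / 2, R - s / 2, by = s),
                      y = seq(-R + s / 2, R - s / 2, by = s))
    xy <- xy[xy$x^2 + xy$y^2 < (R - s / 2)^2, , drop = FALSE]
    if (nrow(xy) == 0) stop("lattice radius too small", call. = FALSE)
    pts <- rbind(pts, cbind(xy$x, xy$y, z))
    z <- z + s
  }
  pts[seq_len(n), , drop = FALSE]
}

# keep a subset of particles (escape cleanup between settling chunks)
.subset_system <- function(system, keep) {
  system$x <- system$x[keep, , drop = FALSE]
  system$v <- system$v[keep, , drop = FALSE]
  system$w <- system$w[keep, , drop = FALSE]
  system$radius <- system$radius[keep]
  system$material <- system$material[keep]
  system$mass <- system$mass[keep]
  system
}

# run until mean kinetic energy per particle stays below `ke_rest` for
# `hold` seconds of simulated time (or `max_time` elapses); particles that
# fall below `drop_below` (open rigs) are removed between chunks so their
# free fall cannot mask rest
.settle <- function(system, walls, max_time, chunk = 0.25, dt = NULL,
                    ke_rest = 1e-8, hold = 0.2, t0 = 0, drop_below = NULL) {
  if (is.null(dt)) dt <- system_timestep(system, 0.25)
  elapsed <- 0; quiet <- 0
  while (elapsed < max_time) {
    res <- dem_run(system, walls, duration = chunk,
                   save_interval = chunk / 2, dt = dt, t0 = t0 + elapsed)
    system <- res$final
    if (!is.null(drop_below)) {
      keep <- system$x[, 3] > drop_below
      if (!all(keep)) system <- .subset_system(system, keep)
      if (!any(keep)) break
    }
    elapsed <- elapsed + chunk
    kepp <- 0.5 * sum(system$mass * rowSums(system$v^2)) / nrow(system$x)
    quiet <- if (kepp < ke_rest) quiet + chunk else 0
    if (quiet >= hold) break
  }
  system
}

# ---- static angle of repose -------------------------------------------------

#' Simulate a static angle-of-repose test
#'
#' Particles are seeded inside a funnel above a flat plate, released under
#' gravity, and left to settle; the heap angle is then estimated with
#' [heap_angle()].  The rig (plate and funnel orifice) scales with the
#' median particle size, mirroring the plate-and-funnel geometry of the
#' physical test at desk scale.
#'
#' @param material a [material_params()].
#' @param n_particles particle budget (a few thousand forms a clear heap;
#'   smaller counts run faster and are noisier).
#' @param seed RNG seed (size sampling and lattice jitter).
#' @param plate_radius,orifice_radius,drop_height rig dimensions (m);
#'   defaults scale from the median particle radius.
#' @param max_time settling-time cap (s).
#' @param dt_fraction Rayleigh fraction.
#' @return list with `angle` (deg), `system` (settled state) and the rig
#'   dimensions; a heap angle below 2 degrees is flagged with a warning
#'   (near-frictionless collapse).
#' @export
simulate_static_aor <- function(material, n_particles = 1200, seed = 1,
                                plate_radius = NULL, orifice_radius = NULL,
                                drop_height = NULL, max_time = 4,
                                dt_fraction = 0.25) {
  set.seed(seed)
  r <- sample_radii(material, n_particles)
  r50 <- stats::median(r)
  rmax <- max(r)
  if (is.null(orifice_radius)) orifice_radius <- 7 * rmax
  if (is.null(plate_radius)) plate_radius <- 10 * r50 + orifice_radius
  # orifice must clear the tallest admissible heap (45 degrees on the plate)
  if (is.null(drop_height)) drop_height <- 1.1 * plate_radius
  s <- 2.1 * rmax
  r_top <- 2.6 * orifice_radius
  funnel_h <- 3.2 * orifice_radius
  # seed a lattice inside the funnel cone (and the cylinder above its rim)
  cone_r <- function(z) {
    frac <- pmin(pmax((z - drop_height) / funnel_h, 0), 1)
    0.9 * (orifice_radius + frac * (r_top - orifice_radius))
  }
  pos <- NULL; z <- drop_height + 2 * rmax
  while (is.null(pos) || nrow(pos) < n_particles) {
    R <- cone_r(z)
    xy <- expand.grid(x = seq(-R + s / 2, R - s / 2, by = s),
                      y = seq(-R + s / 2, R - s / 2, by = s))
    xy <- xy[xy$x^2 + xy$y^2 < (R - s / 2)^2, , drop = FALSE]
    if (nrow(xy)) pos <- rbind(pos, cbind(xy$x, xy$y, z))
    z <- z + s
  }
  pos <- pos[seq_len(n_particles), , drop = FALSE]
  pos[, 1:2] <- pos[, 1:2] + matrix(runif(2 * n_particles, -0.05, 0.05) * s,
                                    ncol = 2)
  sys <- particle_system(pos, r, rep(1L, n_particles),
                         setNames(list(material), material$name))
  plate <- wall(mesh_plate(plate_radius, 0, n = 40))
  funnel <- wall(mesh_funnel(r_top, orifice_radius, funnel_h, drop_height,
                             n = 36))
  sys <- .settle(sys, list(plate, funnel), max_time,
                 dt = system_timestep(sys, dt_fraction),
                 drop_below = -10 * rmax)
  on_plate <- sqrt(sys$x[, 1]^2 + sys$x[, 2]^2) < plate_radius &
    sys$x[, 3] > -rmax
  ang <- heap_angle(sys$x[on_plate, , drop = FALSE], sys$radius[on_plate])
  if (ang < 2)
    warning("heap collapsed to a monolayer (angle < 2 deg): ",
            "material may be effectively frictionless", call. = FALSE)
  list(angle = ang, system = sys, plate_radius = plate_radius,
       orifice_radius = orifice_radius)
}

# ---- dynamic angle of repose ------------------------------------------------

#' Simulate a dynamic angle-of-repose (rotating drum) test
#'
#' A closed drum, filled to the target volume fraction and rotated about
#' its horizontal axis; after a spin-up period the free-surface angle is
#' estimated with [surface_angle()] on several snapshots and averaged.
#'
#' @param material a [material_params()].
#' @param n_particles particle budget.
#' @param rpm drum speed (default 25).
#' @param fill target fill level, v/v (default 0.30).
#' @param seed RNG seed.
#' @param drum_radius,drum_length drum dimensions (m); defaults scale with
#'   particle size to hold `n_particles` at `fill`.
#' @param spin_up rotation time before measurement (s).
#' @param n_snapshots snapshots averaged (>= 5).
#' @param dt_fraction Rayleigh fraction.
#' @return list with `angle` (mean, deg), `sd`, per-snapshot `angles`,
#'   `r_squared` of the last surface fit, and the final `system`.  A mean
#'   surface-fit R^2 below 0.8 is flagged (cataracting regime).
#' @export
simulate_dynamic_aor <- function(material, n_particles = 1200, rpm = 25,
                                 fill = 0.30, seed = 1, drum_radius = NULL,
                                 drum_length = NULL, spin_up = 1.5,
                                 n_snapshots = 5, dt_fraction = 0.25) {
  set.seed(seed)
  r <- sample_radii(material, n_particles)
  r50 <- stats::median(r)
  vol_solid <- sum(4 / 3 * pi * r^3) / 0.58       # random-packing estimate
  s <- 2.1 * max(r)
  if (is.null(drum_length)) drum_length <- 16 * r50
  if (is.null(drum_radius)) {
    drum_radius <- sqrt(vol_solid / (fill * pi * drum_length))
    # the seeding lattice must hold the budget despite edge losses
    r_need <- s + sqrt(1.4 * n_particles * s^3 /
                       (pi * (drum_length - 2 * s)))
    drum_radius <- max(drum_radius, r_need)
  }
  drum <- mesh_drum(drum_radius, drum_length, n = 40)
  w <- wall(drum, axis_point = c(0, 0, 0), axis_dir = c(0, 1, 0), rpm = rpm)
  # seed a block in the lower half of the drum
  g <- expand.grid(x = seq(-drum_radius + s, drum_radius - s, by = s),
                   y = seq(-drum_length / 2 + s, drum_length / 2 - s, by = s),
                   z = seq(-drum_radius + s, drum_radius - s, by = s))
  ok <- sqrt(g$x^2 + g$z^2) < drum_radius - s
  g <- g[ok, , drop = FALSE]
  g <- g[order(g$z), , drop = FALSE]
  if (nrow(g) < n_particles)
    stop("drum too small for the particle budget", call. = FALSE)
  pos <- as.matrix(g[seq_len(n_particles), ])
  pos <- pos + matrix(runif(3 * n_particles, -0.05, 0.05) * s, ncol = 3)
  sys <- particle_system(pos, r, rep(1L, n_particles),
                         setNames(list(material), material$name))
  dt <- system_timestep(sys, dt_fraction)
  sys <- .settle(sys, list(w0 <- wall(drum)), max_time = 1.5, dt = dt)
  res <- dem_run(sys, list(w), duration = spin_up, save_interval = spin_up,
                 dt = dt)
  # measurement phase: one snapshot per eighth of a revolution
  gap <- max(60 / rpm / 8, 0.05)
  angs <- numeric(n_snapshots); r2 <- numeric(n_snapshots)
  sys2 <- res$final
  t_now <- spin_up
  for (k in seq_len(n_snapshots)) {
    res2 <- dem_run(sys2, list(w), duration = gap, save_interval = gap,
                    dt = dt, t0 = t_now)
    sys2 <- res2$final
    t_now <- t_now + gap
    sa <- surface_angle(sys2$x, sys2$radius, drum_radius)
    angs[k] <- sa$angle; r2[k] <- sa$r_squared
  }
  if (mean(r2, na.rm = TRUE) < 0.8)
    warning("surface fit R^2 < 0.8: flow may be cataracting", call. = FALSE)
  list(angle = mean(angs), sd = sd(angs), angles = angs,
       r_squared = r2[n_snapshots], system = sys2)
}

# ---- basic flow energy ------------------------------------------------------

#' FT4-style rheometer rig description
#'
#' @param vessel_diameter,vessel_height vessel dimensions (m); defaults
#'   25 x 50 mm.
#' @param blade_diameter blade span (m); default 23.5 mm.
#' @param helix_angle_deg blade path helix angle (deg); default -5.
#' @param tip_speed_test,tip_speed_conditioning blade tip speeds (m/s);
#'   defaults 100 and 40 mm/s.
#' @param scale geometric scale factor applied to all lengths (desk
#'   fixtures enlarge the rig with the upscaled particles).
#' @return object of class `rheometer_rig`.
#' @export
rheometer_rig <- function(vessel_diameter = 0.025, vessel_height = 0.050,
                          blade_diameter = 0.0235, helix_angle_deg = -5,
                          tip_speed_test = 0.100,
                          tip_speed_conditioning = 0.040, scale = 1) {
  structure(list(vessel_radius = scale * vessel_diameter / 2,
                 vessel_height = scale * vessel_height,
                 blade_radius = scale * blade_diameter / 2,
                 helix_angle_deg = helix_angle_deg,
                 tip_speed_test = tip_speed_test,
                 tip_speed_conditioning = tip_speed_conditioning),
            class = "rheometer_rig")
}

#' Basic flow energy from a blade trace
#'
#' Trapezoidal evaluation of the flow-energy integral
#' `E = int_0^h (T / (R tan|alpha|) + F) dh` over the downward test
#' traverse: `T` blade torque, `F` axial force, `R` blade radius, `alpha`
#' the helix angle.
#'
#' @param trace data frame (or list) with equal-length numeric columns
#'   `h` (penetration depth, m), `torque` (N m) and `force` (N).
#' @param rig a [rheometer_rig()].
#' @return energy in joules.
#' @export
bfe_energy <- function(trace, rig) {
  al <- rig$helix_angle_deg * pi / 180
  if (abs(tan(al)) < 1e-12)
    stop("zero helix angle: flow-energy integrand undefined", call. = FALSE)
  h <- trace$h; Tq <- trace$torque; Fz <- trace$force
  if (length(h) != length(Tq) || length(h) != length(Fz))
    stop("trace columns must have equal length", call. = FALSE)
  if (is.unsorted(h)) stop("penetration depth must be monotone", call. = FALSE)
  integrand <- Tq / (rig$blade_radius * abs(tan(al))) + Fz
  if (length(h) < 2) return(0)
  sum(diff(h) * (head(integrand, -1) + integrand[-1]) / 2)
}

#' Simulate a basic-flow-energy test
#'
#' Fills the vessel, settles the bed, and drives the pitched two-bladed
#' impeller down through it while rotating (counterclockwise test cycle at
#' the test tip speed), recording blade torque and axial force; a
#' conditioning pass (slow clockwise) can be interleaved between test
#' cycles.  The BFE is [bfe_energy()] over the downward test traverse.
#'
#' @param material a [material_params()].
#' @param rig a [rheometer_rig()]; scale it so the vessel holds a few
#'   hundred to a few thousand upscaled particles.
#' @param n_particles particle budget.
#' @param seed RNG seed.
#' @param cycles number of test cycles (conditioning between them).
#' @param condition run a conditioning pass before each test cycle.
#' @param depth_fraction fraction of the bed depth traversed.
#' @param dt_fraction Rayleigh fraction.
#' @return list with `bfe` (J), `trace` (depth/torque/force of the last
#'   test traverse), and the final `system`.
#' @export
simulate_bfe <- function(material, rig = rheometer_rig(), n_particles = 800,
                         seed = 1, cycles = 1, condition = TRUE,
                         depth_fraction = 0.6, dt_fraction = 0.25) {
  set.seed(seed)
  r <- sample_radii(material, n_particles)
  rmax <- max(r)
  if (rig$vessel_radius < 4 * rmax)
    stop("vessel too small for the particle size; increase rig scale",
         call. = FALSE)
  s <- 2.1 * rmax
  pos <- .lattice_cylinder(n_particles, rig$vessel_radius - s / 2, s, s)
  pos[, 1:2] <- pos[, 1:2] +
    matrix(runif(2 * n_particles, -0.05, 0.05) * s, ncol = 2)
  if (n_particles < 1) stop("empty vessel", call. = FALSE)
  sys <- particle_system(pos, r, rep(1L, n_particles),
                         setNames(list(material), material$name))
  vessel <- wall(mesh_vessel(rig$vessel_radius, rig$vessel_height, n = 36))
  dt <- system_timestep(sys, dt_fraction)
  sys <- .settle(sys, list(vessel), max_time = 2, dt = dt)
  bed_top <- max(sys$x[, 3] + sys$radius)
  travel <- depth_fraction * bed_top
  al <- abs(rig$helix_angle_deg) * pi / 180
  run_pass <- function(sys, tip, omega_sign, z_from, z_to) {
    vz <- if (z_from > z_to) -tip * tan(al) else tip * tan(al)
    dur <- abs(z_from - z_to) / abs(vz)
    blade <- wall(mesh_blade(rig$blade_radius, 4 * rmax,
                             rig$helix_angle_deg, z = z_from),
                  axis_point = c(0, 0, 0), axis_dir = c(0, 0, 1),
                  rpm = omega_sign * tip / rig$blade_radius * 60 / (2 * pi),
                  v_trans = c(0, 0, vz))
    nsave <- 40
    res <- dem_run(sys, list(vessel, blade), duration = dur,
                   save_interval = dur / nsave, dt = dt)
    list(res = res, dur = dur, vz = vz)
  }
  trace <- NULL
  for (cy in seq_len(cycles)) {
    if (condition) {
      # conditioning: slow clockwise pass down and up
      cnd <- run_pass(sys, rig$tip_speed_conditioning, +1,
                      bed_top + 2 * rmax, bed_top - travel)
      sys <- cnd$res$final
      cnd <- run_pass(sys, rig$tip_speed_conditioning, +1,
                      bed_top - travel, bed_top + 2 * rmax)
      sys <- cnd$res$final
      sys <- .settle(sys, list(vessel), max_time = 1, dt = dt)
    }
    tst <- run_pass(sys, rig$tip_speed_test, -1,
                    bed_top + 2 * rmax, bed_top - travel)
    sys <- tst$res$final
    # blade loads come from the second wall (the blade); penetration depth
    # is measured from the bed surface downward
    tq <- tst$res$wall_torque[, 2]
    fz <- tst$res$wall_axial_force[, 2]     # reaction on the blade, +z up
    tt <- tst$res$times
    z_blade <- (bed_top + 2 * rmax) + tst$vz * tt
    h <- pmax(bed_top - z_blade, 0)
    trace <- data.frame(h = h, torque = abs(tq), force = pmax(fz, 0))
  }
  list(bfe = bfe_energy(trace, rig), trace = trace, system = sys)
}
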