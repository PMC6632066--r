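# Scalar contact-mechanics primitives of the Hertz-Mindlin (no-slip) and
# JKR models.  These are the reference formulas; the compiled engine in
# src/ applies the same expressions pairwise and a consistency test keeps
# the two in step.

#' Hertz normal elastic force
#'
#' `F_n = (4/3) E* sqrt(R*) dn^(3/2)`; zero for non-positive overlap (the
#' plain Hertz contact carries no cohesion).
#'
#' @param overlap normal overlap `dn` in metres (vectorised).
#' @param Estar equivalent Young's modulus (Pa).
#' @param Rstar equivalent radius (m).
#' @return force magnitude in newtons.
#' @export
hertz_normal_force <- function(overlap, Estar, Rstar) {
  ifelse(overlap > 0, (4 / 3) * Estar * sqrt(Rstar) * overlap^1.5, 0)
}

#' Damping ratio from the coefficient of restitution
#'
#' `beta = -ln(e) / sqrt(ln(e)^2 + pi^2)`, in \[0, 1): zero for a
#' perfectly elastic contact, approaching 1 as e tends to 0.
#'
#' @param e coefficient of restitution in (0, 1].
#' @export
damping_ratio <- function(e) {
  if (any(e <= 0 | e > 1)) stop("restitution must lie in (0, 1]", call. = FALSE)
  le <- log(e)
  -le / sqrt(le^2 + pi^2)
}

#' Viscous normal damping force
#'
#' `F_nd = -2 sqrt(5/6) beta sqrt(Sn m*) v_n_rel`, opposing the normal
#' relative velocity; zero when `beta = 0` (e = 1).
#'
#' @param beta damping ratio (see [damping_ratio()]).
#' @param Sn normal contact stiffness `2 E* sqrt(R* dn)` (N/m).
#' @param mstar equivalent mass (kg).
#' @param vn_rel normal relative velocity (scalar or vector, m/s).
#' @return force with the same shape as `vn_rel` (N).
#' @export
normal_damping_force <- function(beta, Sn, mstar, vn_rel) {
  if (Sn < 0 || mstar <= 0) stop("need Sn >= 0 and m* > 0", call. = FALSE)
  -2 * sqrt(5 / 6) * beta * sqrt(Sn * mstar) * vn_rel
}

#' Tangential contact force with Coulomb cap
#'
#' Mindlin no-slip spring `-St dt` plus viscous damping
#' `-2 sqrt(5/6) beta sqrt(St m*) v_t_rel`, with the total magnitude capped
#' at `mu_s |Fn|`; when the cap engages, the accumulated tangential
#' displacement is rescaled back onto the friction cone.
#'
#' @param St tangential stiffness `8 G* sqrt(R* dn)` (N/m).
#' @param delta_t accumulated tangential displacement vector (m).
#' @param beta damping ratio.
#' @param mstar equivalent mass (kg).
#' @param vt_rel tangential relative velocity vector (m/s).
#' @param mu_s static friction coefficient.
#' @param Fn normal force magnitude used for the Coulomb limit (N).
#' @return list with `force` (vector, N) and the possibly rescaled
#'   `delta_t`.
#' @export
tangential_force <- function(St, delta_t, beta, mstar, vt_rel, mu_s, Fn) {
  Ft <- -St * delta_t - 2 * sqrt(5 / 6) * beta * sqrt(St * mstar) * vt_rel
  mag <- sqrt(sum(Ft^2))
  cap <- mu_s * abs(Fn)
  if (mag > cap && mag > 0) {
    Ft <- Ft * (cap / mag)
    if (St > 0) delta_t <- -Ft / St       # slide: spring sits on the cone
  }
  list(force = Ft, delta_t = delta_t)
}

#' Rolling-friction torque
#'
#' Constant-directional torque `T = -mu_r |Fn| R_p unit(omega)` opposing
#' the particle's angular velocity; zero for a non-spinning particle.
#'
#' @param mu_r rolling friction coefficient.
#' @param Fn normal force magnitude (N).
#' @param Rp distance from the contact point to the particle centre (m).
#' @param omega angular velocity vector (rad/s).
#' @return torque vector (N m).
#' @export
rolling_torque <- function(mu_r, Fn, Rp, omega) {
  wmag <- sqrt(sum(omega^2))
  if (wmag == 0 || mu_r == 0) return(c(0, 0, 0))
  -mu_r * abs(Fn) * Rp * omega / wmag
}

#' JKR normal force as a function of contact radius
#'
#' `F_JKR = -4 sqrt(pi gamma E*) a^(3/2) + (4 E* / (3 R*)) a^3` (positive =
#' repulsive).  With `gamma = 0` and `a = sqrt(R* dn)` this reduces exactly
#' to the Hertz force; its minimum over `a` is the pull-off force
#' `-3 pi gamma R*`.
#'
#' @param a contact radius (m, vectorised).
#' @param gamma surface energy (J/m^2).
#' @param Estar equivalent Young's modulus (Pa).
#' @param Rstar equivalent radius (m).
#' @return signed force (N).
#' @export
jkr_normal_force <- function(a, gamma, Estar, Rstar) {
  if (any(a < 0) || gamma < 0) stop("need a >= 0 and gamma >= 0", call. = FALSE)
  -4 * sqrt(pi * gamma * Estar) * a^1.5 + (4 * Estar / (3 * Rstar)) * a^3
}

#' JKR pull-off (detachment) force magnitude
#'
#' Closed form `3 pi gamma R*` for the force convention of
#' [jkr_normal_force()].
#'
#' @inheritParams jkr_normal_force
#' @export
jkr_pulloff_force <- function(gamma, Rstar) 3 * pi * gamma * Rstar

#' JKR contact radius from the normal overlap
#'
#' Solves `dn = a^2/R* - sqrt(4 pi gamma a / E*)` for `a` by Newton
#' iteration.  The overlap-radius relation admits tensile (negative
#' overlap) contacts down to the detachment overlap; beyond it the contact
#' has snapped off and `NA` is returned.
#'
#' @param overlap normal overlap `dn` (m); may be negative for a stretched
#'   adhesive neck.
#' @inheritParams jkr_normal_force
#' @return contact radius (m), or `NA` past detachment.
#' @export
jkr_contact_radius <- function(overlap, gamma, Estar, Rstar) {
  if (gamma == 0) return(ifelse(overlap > 0, sqrt(Rstar * overlap), 0))
  cc <- sqrt(4 * pi * gamma / Estar)
  # stationary point of dn(a): the smallest admissible overlap
  a_c <- (cc * Rstar / 4)^(2 / 3)
  d_min <- a_c^2 / Rstar - cc * sqrt(a_c)
  out <- vapply(overlap, function(d) {
    if (d < d_min) return(NA_real_)
    a <- max(sqrt(Rstar * max(d, 0)), 2 * a_c)   # start on the outer branch
    for (i in 1:60) {
      f <- a^2 / Rstar - cc * sqrt(a) - d
      fp <- 2 * a / Rstar - cc / (2 * sqrt(a))
      step <- f / fp
      a_new <- a - step
      if (a_new < a_c) a_new <- (a + a_c) / 2    # stay on the stable branch
      if (abs(a_new - a) < 1e-15 + 1e-12 * a) { a <- a_new; break }
      a <- a_new
    }
    a
  }, numeric(1))
  out
}

#' Rayleigh-wave stable time step
#'
#' `dt = fraction * min_p pi R_p sqrt(rho_p / G_p) / (0.1631 nu_p + 0.8766)`
#' over all particles: the usual DEM stability criterion tied to the
#' surface-wave period of the smallest, stiffest particle.
#'
#' @param radius particle radii (m).
#' @param density particle densities (kg/m^3).
#' @param shear_modulus shear moduli (Pa).
#' @param poisson Poisson ratios.
#' @param fraction fraction of the Rayleigh time (common choices 0.1-0.3).
#' @return stable time step in seconds.
#' @export
rayleigh_timestep <- function(radius, density, shear_modulus, poisson,
                              fraction = 0.25) {
  if (length(radius) == 0) stop("need at least one particle", call. = FALSE)
  if (fraction <= 0) stop("'fraction' must be positive", call. = FALSE)
  tr <- pi * radius * sqrt(density / shear_modulus) /
    (0.1631 * poisson + 0.8766)
  fraction * min(tr)
}
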