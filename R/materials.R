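# Material definitions for the DEM engine.  Sizes are entered pre-scaling
# in micrometres (as measured by laser diffraction); the engine works in SI
# after applying the particle-size scale factor.

#' Define a DEM material
#'
#' Holds the measured particle sizes, elastic constants and calibrated
#' interaction coefficients for one powder, for both particle-particle
#' (`*_pp`) and particle-wall (`*_pw`) pairings.
#'
#' @param name material name.
#' @param d10,d50,d90 particle diameters in micrometres (pre-scaling).
#' @param true_density true (pycnometric) density in g/cm^3.
#' @param poisson Poisson's ratio, in \[0, 0.5).
#' @param shear_modulus shear modulus G in Pa.
#' @param surface_energy JKR surface energy gamma in J/m^2 (0 disables
#'   cohesion; the cohesive path reduces exactly to Hertz at 0).
#' @param e_pp,e_pw coefficients of restitution, in (0, 1].
#' @param mu_s_pp,mu_s_pw coefficients of static friction (>= 0).
#' @param mu_r_pp,mu_r_pw coefficients of rolling friction (>= 0).
#' @param size_scale particle-size upscale factor (default 100, the usual
#'   coarse-graining for fine pharmaceutical powders).
#' @return object of class `material_params`.
#' @export
material_params <- function(name, d10, d50, d90, true_density, poisson,
                            shear_modulus, surface_energy = 0,
                            e_pp, e_pw = e_pp,
                            mu_s_pp, mu_s_pw = mu_s_pp,
                            mu_r_pp, mu_r_pw = mu_r_pp,
                            size_scale = 100) {
  if (true_density <= 0) stop("density must be positive", call. = FALSE)
  if (poisson < 0 || poisson >= 0.5)
    stop("Poisson's ratio must lie in [0, 0.5)", call. = FALSE)
  if (shear_modulus <= 0) stop("shear modulus must be positive", call. = FALSE)
  if (surface_energy < 0) stop("surface energy must be >= 0", call. = FALSE)
  for (e in c(e_pp, e_pw))
    if (e <= 0 || e > 1) stop("restitution must lie in (0, 1]", call. = FALSE)
  if (any(c(mu_s_pp, mu_s_pw, mu_r_pp, mu_r_pw) < 0))
    stop("friction coefficients must be >= 0", call. = FALSE)
  if (!(d10 <= d50 && d50 <= d90) || d10 <= 0)
    stop("need 0 < d10 <= d50 <= d90", call. = FALSE)
  structure(list(name = name, d10 = d10, d50 = d50, d90 = d90,
                 true_density = true_density, poisson = poisson,
                 shear_modulus = shear_modulus,
                 surface_energy = surface_energy,
                 e_pp = e_pp, e_pw = e_pw,
                 mu_s_pp = mu_s_pp, mu_s_pw = mu_s_pw,
                 mu_r_pp = mu_r_pp, mu_r_pw = mu_r_pw,
                 size_scale = size_scale),
            class = "material_params")
}

#' Default wall material (stainless steel process equipment)
#'
#' @param poisson,shear_modulus,density elastic constants of the wall.
#' @return a minimal wall-material list used for particle-wall contacts.
#' @export
wall_material <- function(poisson = 0.30, shear_modulus = 7e10,
                          density = 7.80) {
  list(name = "stainless_steel", poisson = poisson,
       shear_modulus = shear_modulus, true_density = density)
}

#' Read a material table from CSV
#'
#' Schema: `material, d10_um, d50_um, d90_um, true_density_g_cm3, poisson,
#' shear_modulus_pa, surface_energy_j_m2, e_pp, e_pw, mu_s_pp, mu_s_pw,
#' mu_r_pp, mu_r_pw`.
#'
#' @param path CSV path.
#' @param size_scale particle-size upscale factor applied by the engine.
#' @return named list of [material_params()].
#' @export
read_materials <- function(path, size_scale = 100) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  mats <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    material_params(r$material, r$d10_um, r$d50_um, r$d90_um,
                    r$true_density_g_cm3, r$poisson, r$shear_modulus_pa,
                    r$surface_energy_j_m2, r$e_pp, r$e_pw,
                    r$mu_s_pp, r$mu_s_pw, r$mu_r_pp, r$mu_r_pw,
                    size_scale = size_scale)
  })
  setNames(mats, df$material)
}

#' @rdname read_materials
#' @param materials named list of [material_params()] to write.
#' @export
write_materials <- function(materials, path) {
  df <- do.call(rbind, lapply(materials, function(m)
    data.frame(material = m$name, d10_um = m$d10, d50_um = m$d50,
               d90_um = m$d90, true_density_g_cm3 = m$true_density,
               poisson = m$poisson, shear_modulus_pa = m$shear_modulus,
               surface_energy_j_m2 = m$surface_energy,
               e_pp = m$e_pp, e_pw = m$e_pw,
               mu_s_pp = m$mu_s_pp, mu_s_pw = m$mu_s_pw,
               mu_r_pp = m$mu_r_pp, mu_r_pw = m$mu_r_pw)))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

# Young's modulus from shear modulus and Poisson's ratio.
.young <- function(G, nu) 2 * G * (1 + nu)

#' Equivalent contact properties for a material pair
#'
#' Standard harmonic combinations used by the Hertz-Mindlin model:
#' `1/E* = (1-nu_a^2)/E_a + (1-nu_b^2)/E_b`, `1/G* = (2-nu_a)/G_a +
#' (2-nu_b)/G_b`, `1/R* = 1/R_a + 1/R_b`, `1/m* = 1/m_a + 1/m_b`.  A wall
#' partner (`material_b = NULL` or [wall_material()]) is treated as
#' infinite in mass and radius.
#'
#' @param material_a,material_b [material_params()] objects (or a wall
#'   partner for `material_b`).
#' @param radius_a,radius_b particle radii in metres (`radius_b = Inf` for
#'   a wall).
#' @param overlap optional normal overlap (m); when given, the normal and
#'   tangential contact stiffnesses `Sn = 2 E* sqrt(R* dn)` and
#'   `St = 8 G* sqrt(R* dn)` are included.
#' @return list with `Estar`, `Gstar`, `Rstar`, `mstar`, `beta` (from the
#'   particle-particle or particle-wall restitution as appropriate) and,
#'   when `overlap` is given, `Sn` and `St`.
#' @export
equivalent_props <- function(material_a, material_b = NULL,
                             radius_a, radius_b = Inf, overlap = NULL) {
  if (radius_a <= 0 || (is.finite(radius_b) && radius_b <= 0))
    stop("radii must be positive", call. = FALSE)
  a <- material_a
  wall <- is.null(material_b) || is.null(material_b$d50)
  b <- if (is.null(material_b)) wall_material() else material_b
  Ea <- .young(a$shear_modulus, a$poisson)
  Eb <- .young(b$shear_modulus, b$poisson)
  Estar <- 1 / ((1 - a$poisson^2) / Ea + (1 - b$poisson^2) / Eb)
  Gstar <- 1 / ((2 - a$poisson) / a$shear_modulus +
                (2 - b$poisson) / b$shear_modulus)
  Rstar <- if (is.finite(radius_b)) 1 / (1 / radius_a + 1 / radius_b)
           else radius_a
  ma <- a$true_density * 1000 * (4 / 3) * pi * radius_a^3
  mstar <- if (is.finite(radius_b)) {
    mb <- b$true_density * 1000 * (4 / 3) * pi * radius_b^3
    1 / (1 / ma + 1 / mb)
  } else ma
  e <- if (wall) a$e_pw else mean(c(a$e_pp, b$e_pp))
  out <- list(Estar = Estar, Gstar = Gstar, Rstar = Rstar, mstar = mstar,
              beta = damping_ratio(e))
  if (!is.null(overlap)) {
    out$Sn <- 2 * Estar * sqrt(Rstar * overlap)
    out$St <- 8 * Gstar * sqrt(Rstar * overlap)
  }
  out
}

# Pair interaction coefficients between two particle materials: restitution
# and friction combine by the arithmetic mean of the per-material
# particle-particle values; JKR surface energy combines by the geometric
# mean (zero against a cohesionless partner).  Particle-wall pairs use the
# material's own particle-wall coefficients.
.pair_coefficients <- function(a, b = NULL) {
  if (is.null(b)) {
    list(e = a$e_pw, mu_s = a$mu_s_pw, mu_r = a$mu_r_pw, gamma = a$surface_energy)
  } else {
    list(e = mean(c(a$e_pp, b$e_pp)),
         mu_s = mean(c(a$mu_s_pp, b$mu_s_pp)),
         mu_r = mean(c(a$mu_r_pp, b$mu_r_pp)),
         gamma = sqrt(a$surface_energy * b$surface_energy))
  }
}
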