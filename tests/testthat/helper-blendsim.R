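# Shared fixtures for the test suite.  Everything is generated in code or
# read from the package's bundled tables.

fx <- study_fixtures()

ref_fits <- list(
  drug_content = fit_rsm(fx$runs, "drug_content",
                         terms = c("x1", "x2", "x3", "x1x2", "x2x3")),
  cu = fit_rsm(fx$runs, "cu", terms = c("x1", "x2", "x3", "x1x3", "x2x3")))

ref_specs <- list(
  drug_content = spec_limits(95, 105, target = "maximize"),
  cu = spec_limits(upper = 5, target = "minimize"))

# a light elastic test material (unit size scale: d50 in um = diameter)
test_material <- function(e = 0.5, mu_s = 0, mu_r = 0, G = 1e7, nu = 0.25,
                          rho = 1.0, gamma = 0) {
  material_params("test", 1000, 2000, 3000, rho, nu, G, gamma,
                  e_pp = e, e_pw = e, mu_s_pp = mu_s, mu_s_pw = mu_s,
                  mu_r_pp = mu_r, mu_r_pw = mu_r, size_scale = 1)
}

# two equal spheres on a head-on collision course, minimal gap
two_sphere_impact <- function(mat, speed = 0.5, r = 1e-3, gap = 4e-6) {
  particle_system(rbind(c(-(r + gap / 2), 0, 0), c(r + gap / 2, 0, 0)),
                  c(r, r), c(1L, 1L), list(test = mat),
                  v = rbind(c(speed, 0, 0), c(-speed, 0, 0)),
                  gravity = c(0, 0, 0))
}
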