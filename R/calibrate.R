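# Iterative calibration of interaction coefficients against experimental
# bulk responses: simulate, compare, adjust, repeat until every response is
# within the relative-bias tolerance.

#' Calibration targets for one material
#'
#' @param targets data frame with columns `test` (e.g. `"aor"`, `"drum"`,
#'   `"bfe"`), `experimental_value` and optionally `unit`.
#' @param tolerance acceptable relative bias (default 0.10, i.e. 10%).
#' @return object of class `calibration_target`.
#' @export
calibration_target <- function(targets, tolerance = 0.10) {
  if (!all(c("test", "experimental_value") %in% names(targets)))
    stop("targets need columns 'test' and 'experimental_value'", call. = FALSE)
  if (nrow(targets) < 1) stop("need at least one target", call. = FALSE)
  if (tolerance <= 0) stop("tolerance must be positive", call. = FALSE)
  structure(list(targets = targets, tolerance = tolerance),
            class = "calibration_target")
}

#' Read a targets CSV (`material, test, experimental_value, unit`)
#'
#' @param path CSV path.
#' @param material optional material name filter.
#' @inheritParams calibration_target
#' @export
read_calibration_targets <- function(path, material = NULL,
                                     tolerance = 0.10) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(material)) df <- df[df$material == material, , drop = FALSE]
  calibration_target(df, tolerance)
}

# default virtual-test registry; each entry simulates one bulk response
.default_simulators <- function(n_particles, seed) {
  list(
    aor = function(mat)
      simulate_static_aor(mat, n_particles = n_particles, seed = seed)$angle,
    drum = function(mat)
      simulate_dynamic_aor(mat, n_particles = n_particles, seed = seed)$angle,
    bfe = function(mat) {
      rmax <- mat$d90 * mat$size_scale * 1e-6 / 2
      simulate_bfe(mat, rheometer_rig(scale = max(1, 10 * rmax / 0.0125)),
                   n_particles = n_particles, seed = seed)$bfe * 1000  # mJ
    })
}

.set_material_param <- function(material, param, value) {
  switch(param,
    mu_s = { material$mu_s_pp <- material$mu_s_pw <- value },
    mu_r = { material$mu_r_pp <- material$mu_r_pw <- value },
    e = { material$e_pp <- material$e_pw <- value },
    poisson = { material$poisson <- value },
    stop("unknown adjustable parameter: ", param, call. = FALSE))
  material
}

.get_material_param <- function(material, param) {
  switch(param, mu_s = material$mu_s_pp, mu_r = material$mu_r_pp,
         e = material$e_pp, poisson = material$poisson)
}

.param_bounds <- function(param) {
  switch(param, mu_s = c(0.01, 1.5), mu_r = c(0, 1.5), e = c(0.05, 0.99),
         poisson = c(0.05, 0.45))
}

#' Calibrate interaction coefficients against bulk-test targets
#'
#' Coordinate descent with step halving over the adjustable parameters
#' (static and rolling friction by default, applied to both
#' particle-particle and particle-wall pairings): at each iteration every
#' parameter tries a step up and down, the candidate with the lowest worst
#' relative bias across all targets is accepted, and steps are halved when
#' no move improves.  Accepts as soon as every simulated response is
#' within the tolerance.
#'
#' @param material starting [material_params()] guess.
#' @param targets a [calibration_target()].
#' @param adjustable parameter names to adjust (default
#'   `c("mu_s", "mu_r")`).
#' @param budget maximum number of bulk-test simulations (default 40).
#' @param simulators named list of functions `f(material) -> value`, one
#'   per target test name; defaults to the package's virtual tests at the
#'   given particle budget and seed.
#' @param n_particles,seed passed to the default simulators.
#' @param step initial step size per parameter.
#' @param verbose print per-evaluation progress.
#' @return list with `material` (calibrated), `converged`, `trail` (audit
#'   data frame: one row per evaluation with parameter values, responses,
#'   worst bias, acceptance flag) and `n_evals`.
#' @export
calibrate <- function(material, targets, adjustable = c("mu_s", "mu_r"),
                      budget = 40, simulators = NULL, n_particles = 700,
                      seed = 1, step = 0.15, verbose = FALSE) {
  stopifnot(inherits(targets, "calibration_target"))
  tdf <- targets$targets
  if (is.null(simulators)) simulators <- .default_simulators(n_particles, seed)
  missing_sims <- setdiff(tdf$test, names(simulators))
  if (length(missing_sims))
    stop("no simulator for test(s): ", paste(missing_sims, collapse = ", "),
         call. = FALSE)
  n_evals <- 0
  trail <- NULL
  evaluate <- function(mat) {
    n_evals <<- n_evals + length(tdf$test)
    sim <- vapply(seq_len(nrow(tdf)), function(i)
      simulators[[tdf$test[i]]](mat), numeric(1))
    bias <- abs(sim - tdf$experimental_value) / abs(tdf$experimental_value)
    list(sim = sim, worst = max(bias))
  }
  log_row <- function(mat, ev, accepted) {
    row <- data.frame(eval = n_evals,
                      t(vapply(adjustable, .get_material_param, numeric(1),
                               material = mat)),
                      worst_bias = ev$worst, accepted = accepted)
    names(row)[2:(1 + length(adjustable))] <- adjustable
    for (i in seq_len(nrow(tdf)))
      row[[paste0("sim_", tdf$test[i])]] <- ev$sim[i]
    trail <<- rbind(trail, row)
  }
  cur <- evaluate(material)
  log_row(material, cur, TRUE)
  if (verbose) message(sprintf("start: worst bias %.3f", cur$worst))
  steps <- setNames(rep(step, length(adjustable)), adjustable)
  while (cur$worst > targets$tolerance && n_evals < budget) {
    improved <- FALSE
    for (p in adjustable) {
      if (n_evals >= budget) break
      b <- .param_bounds(p)
      v0 <- .get_material_param(material, p)
      for (dir in c(1, -1)) {
        v1 <- min(max(v0 + dir * steps[p], b[1]), b[2])
        if (abs(v1 - v0) < 1e-9) next
        cand <- .set_material_param(material, p, v1)
        ev <- evaluate(cand)
        better <- ev$worst < cur$worst - 1e-9
        log_row(cand, ev, better)
        if (verbose)
          message(sprintf("  %s = %.3f -> worst bias %.3f%s", p, v1,
                          ev$worst, if (better) " *" else ""))
        if (better) {
          material <- cand; cur <- ev; improved <- TRUE
          break
        }
        if (n_evals >= budget) break
      }
      if (cur$worst <= targets$tolerance) break
    }
    if (!improved) {
      steps <- steps / 2
      if (all(steps < 0.01)) break
    }
  }
  list(material = material, converged = cur$worst <= targets$tolerance,
       worst_bias = cur$worst, trail = trail, n_evals = n_evals)
}
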