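# Every input needed to exercise the pipeline without downloads: the
# study's printed tables shipped as CSV, synthetic DoE tables with known
# ground truth, and miniature particle scenes sized for desk runs.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "blendsim")
  if (path == "") stop("missing bundled data file: ", file, call. = FALSE)
  path
}

#' Factor definitions of the blending DoE
#'
#' Filling level 30-70% (centre 50), rotational speed 15-25 rpm (centre
#' 20), blending time 9-24 min (centre 16.5).
#'
#' @return list of three [factor_def()].
#' @export
blending_factors <- function() {
  list(factor_def("filling_level", 30, 70),
       factor_def("rotational_speed", 15, 25),
       factor_def("blending_time", 9, 24))
}

#' Bundled study tables
#'
#' Returns the study's input tables as typed objects: the 12-row risk
#' register, the 15-run Box-Behnken table with measured drug content, CU
#' and Carr index, the optimal-setting validation table, the material
#' parameter table, and the BFE calibration targets.
#'
#' @return list with `register`, `runs` (with `"factors"` attribute),
#'   `optimal`, `materials`, `bfe_targets`, `formulation`.
#' @export
study_fixtures <- function() {
  runs <- read_runs(.extdata("doe_runs.csv"),
                    factors = blending_factors())
  list(register = read_risk_register(.extdata("risk_register.csv")),
       runs = runs,
       optimal = read.csv(.extdata("optimal_settings.csv")),
       materials = read_materials(.extdata("materials.csv")),
       bfe_targets = read.csv(.extdata("bfe_targets.csv")),
       formulation = amlodipine_formulation())
}

#' Synthetic Box-Behnken response table with known coefficients
#'
#' Evaluates a coded-scale polynomial with the given true coefficients on
#' the 3-factor Box-Behnken design and adds Gaussian noise, for fit
#' recovery and power studies.
#'
#' @param coefficients named numeric vector: `intercept` plus any of the
#'   model terms (`x1`, `x2`, `x1x2`, `x1^2`, ...).
#' @param noise_sd response noise SD (default 0.27, near the residual
#'   scale of content-like responses).
#' @param factors list of [factor_def()] (default [blending_factors()]).
#' @param center_runs replicated centre points.
#' @param seed RNG seed.
#' @param response name for the response column.
#' @return run table (as [build_bbd()]) with the response appended; the
#'   truth is attached as attribute `"true_coefficients"`.
#' @export
synth_doe <- function(coefficients, noise_sd = 0.27,
                      factors = blending_factors(), center_runs = 3,
                      seed = 1, response = "y") {
  if (noise_sd < 0) stop("noise SD must be >= 0", call. = FALSE)
  if (!"intercept" %in% names(coefficients))
    stop("coefficients must include 'intercept'", call. = FALSE)
  runs <- build_bbd(factors, center_runs = center_runs, seed = seed)
  coded <- runs[, c("x1", "x2", "x3")]
  y <- rep(coefficients[["intercept"]], nrow(runs))
  for (term in setdiff(names(coefficients), "intercept"))
    y <- y + coefficients[[term]] * .term_column(term, coded)
  set.seed(seed + 1L)
  runs[[response]] <- y + rnorm(nrow(runs), 0, noise_sd)
  attr(runs, "true_coefficients") <- coefficients
  attr(runs, "factors") <- factors
  runs
}

#' Desk-scale materials for miniature simulations
#'
#' The formulation's five components with per-component size scales chosen
#' so every particle lands near 2 mm radius, and a softened shear modulus
#' of 1e5 Pa (bulk behaviour is insensitive to G over a wide range, and the
#' softer value lengthens the stable time step by an order of magnitude).
#' Also provides `desk_powder`, a single generic free-flowing powder used
#' by the heap and drum fixtures.
#'
#' @param shear_modulus shear modulus for the desk variants (Pa).
#' @return named list of [material_params()].
#' @export
desk_materials <- function(shear_modulus = 1e5) {
  full <- read_materials(.extdata("materials.csv"))
  scales <- c(amlodipine_besylate = 400, smcc_90 = 40, pvp_k25 = 64,
              ccm_na = 80, st_mg = 700)
  out <- lapply(names(scales), function(nm) {
    m <- full[[nm]]
    m$size_scale <- scales[[nm]]
    m$shear_modulus <- shear_modulus
    m
  })
  names(out) <- names(scales)
  out$desk_powder <- material_params(
    "desk_powder", 2500, 3000, 3500, 1.40, 0.30, shear_modulus, 0,
    e_pp = 0.30, e_pw = 0.30, mu_s_pp = 0.50, mu_s_pw = 0.50,
    mu_r_pp = 0.30, mu_r_pw = 0.30, size_scale = 1)
  out
}

#' Miniature particle scenes
#'
#' Deterministic-by-seed scenes sized for desk runs: `two_body` (a
#' collision course), `heap` (funnel charge above a plate), `drum` (filled
#' rotating drum), `vessel` (settled cylindrical bed), `v_blender` and
#' `double_cone` (recipe-filled blenders in the segregated initial state).
#'
#' @param kind scene kind.
#' @param budget particle budget.
#' @param seed RNG seed.
#' @param rpm rotation speed for the rotating scenes.
#' @param ... forwarded to the underlying builders.
#' @return list with `system`, `walls` and scene metadata (`blender`,
#'   `formulation` where applicable).
#' @export
mini_scene <- function(kind = c("two_body", "heap", "drum", "vessel",
                                "v_blender", "double_cone"),
                       budget = 2000, seed = 1, rpm = 24, ...) {
  kind <- match.arg(kind)
  if (budget < 1) stop("budget must be >= 1", call. = FALSE)
  dm <- desk_materials()
  if (kind == "two_body") {
    m <- dm$desk_powder
    r <- m$d50 * 1e-6 / 2
    sys <- particle_system(rbind(c(-1.05 * r, 0, 0), c(1.05 * r, 0, 0)),
                           c(r, r), c(1L, 1L), list(desk_powder = m),
                           v = rbind(c(0.5, 0, 0), c(-0.5, 0, 0)),
                           gravity = c(0, 0, 0))
    return(list(system = sys, walls = list()))
  }
  if (kind == "heap") {
    m <- dm$desk_powder
    set.seed(seed)
    r <- sample_radii(m, budget)
    rmax <- max(r)
    orif <- 7 * rmax
    s <- 2.1 * rmax
    pos <- .lattice_cylinder(budget, orif * 2.2, 4 * stats::median(r), s)
    pos[, 1:2] <- pos[, 1:2] +
      matrix(runif(2 * budget, -0.05, 0.05) * s, ncol = 2)
    sys <- particle_system(pos, r, rep(1L, budget),
                           list(desk_powder = m))
    plate <- wall(mesh_plate(10 * stats::median(r) + orif, 0, n = 40))
    funnel <- wall(mesh_funnel(2.6 * orif, orif, 3.2 * orif,
                               4 * stats::median(r), n = 36))
    return(list(system = sys, walls = list(plate, funnel)))
  }
  if (kind %in% c("v_blender", "double_cone")) {
    mats <- dm[names(amlodipine_formulation()$components)]
    # blender sized so `budget` d50 particles make a 30% fill
    solid <- mean(vapply(mats, function(m) {
      r50 <- m$d50 * m$size_scale * 1e-6 / 2
      4 / 3 * pi * r50^3
    }, numeric(1))) * budget
    vol_l <- solid / 0.58 / 0.30 * 1000
    blender <- build_blender(if (kind == "v_blender") "v" else "double_cone",
                             volume_l = vol_l, rpm = rpm, ...)
    form <- amlodipine_formulation()
    sys <- fill_blender(blender, form, mats, fill_fraction = 0.30,
                        budget = budget, seed = seed)
    return(list(system = sys, walls = list(blender), blender = blender,
                formulation = form))
  }
  # vessel / drum
  m <- dm$desk_powder
  set.seed(seed)
  r <- sample_radii(m, budget)
  s <- 2.1 * max(r)
  if (kind == "vessel") {
    R <- 9 * stats::median(r)
    pos <- .lattice_cylinder(budget, R - s / 2, s, s)
    pos[, 1:2] <- pos[, 1:2] +
      matrix(runif(2 * budget, -0.05, 0.05) * s, ncol = 2)
    sys <- particle_system(pos, r, rep(1L, budget),
                           list(desk_powder = m))
    return(list(system = sys,
                walls = list(wall(mesh_vessel(R, 40 * stats::median(r),
                                              n = 36)))))
  }
  # drum
  vol_solid <- sum(4 / 3 * pi * r^3) / 0.58
  len <- 16 * stats::median(r)
  R <- max(sqrt(vol_solid / (0.30 * pi * len)),
           s + sqrt(1.4 * budget * s^3 / (pi * (len - 2 * s))))
  drum <- mesh_drum(R, len, n = 40)
  g <- expand.grid(x = seq(-R + s, R - s, by = s),
                   y = seq(-len / 2 + s, len / 2 - s, by = s),
                   z = seq(-R + s, R - s, by = s))
  g <- g[sqrt(g$x^2 + g$z^2) < R - s, , drop = FALSE]
  g <- g[order(g$z), , drop = FALSE]
  if (nrow(g) < budget) stop("drum too small for budget", call. = FALSE)
  pos <- as.matrix(g[seq_len(budget), ])
  pos <- pos + matrix(runif(3 * budget, -0.05, 0.05) * s, ncol = 3)
  sys <- particle_system(pos, r, rep(1L, budget), list(desk_powder = m))
  list(system = sys,
       walls = list(wall(drum, axis_dir = c(0, 1, 0), rpm = rpm)))
}
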