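# End-to-end blending: blender geometry, recipe-based filling, rotation,
# cylinder-bin sampling, drug content / content uniformity, Carr index and
# T-index bookkeeping, and simulation-vs-experiment regression comparison.

#' Carr (compressibility) index
#'
#' `(tap - bulk) / tap x 100`; lower values indicate better flow.
#'
#' @param bulk_density,tap_density densities in consistent units, with
#'   `0 < bulk <= tap`.
#' @return percent.
#' @export
carr_index <- function(bulk_density, tap_density) {
  if (any(bulk_density <= 0) || any(tap_density <= 0))
    stop("densities must be positive", call. = FALSE)
  if (any(bulk_density > tap_density))
    stop("bulk density cannot exceed tap density", call. = FALSE)
  (tap_density - bulk_density) / tap_density * 100
}

#' Define a formulation (recipe)
#'
#' @param components named numeric vector of mass fractions summing to 1.
#' @param api name of the active ingredient component (exactly one).
#' @return object of class `formulation` with the nominal API fraction.
#' @export
formulation <- function(components, api) {
  if (abs(sum(components) - 1) > 1e-9)
    stop("mass fractions must sum to 1", call. = FALSE)
  if (!api %in% names(components) || length(api) != 1L)
    stop("'api' must name exactly one component", call. = FALSE)
  structure(list(components = components, api = api,
                 nominal_api_fraction = unname(components[api])),
            class = "formulation")
}

#' The amlodipine direct-compression formulation
#'
#' Amlodipine besylate 6.935% w/w (API), SMCC 90 77.065%, PVP K25 4.5%,
#' CCM-Na 10%, St-Mg 1.5%.
#'
#' @return a [formulation()].
#' @export
amlodipine_formulation <- function() {
  formulation(c(amlodipine_besylate = 0.06935, smcc_90 = 0.77065,
                pvp_k25 = 0.045, ccm_na = 0.10, st_mg = 0.015),
              api = "amlodipine_besylate")
}

#' Build a blender wall with kinematics
#'
#' Constructs a watertight V-blender or double-cone mesh at the nominal
#' volume (checked to 5%) rotating about a horizontal axis at the given
#' speed.
#'
#' @param type `"v"` or `"double_cone"`.
#' @param volume_l nominal volume in litres.
#' @param rpm rotation speed.
#' @param ... forwarded to [mesh_vblender()] / [mesh_doublecone()].
#' @return a [wall()]; the mesh (with its `inside` predicate) is in
#'   `$mesh`, the nominal volume in `attr(, "nominal_volume_l")`.
#' @export
build_blender <- function(type = c("v", "double_cone"), volume_l, rpm, ...) {
  type <- match.arg(type)
  mesh <- switch(type, v = mesh_vblender(volume_l, ...),
                 double_cone = mesh_doublecone(volume_l, ...))
  if (!mesh_is_watertight(mesh))
    stop("generated blender mesh is not watertight", call. = FALSE)
  vol <- mesh_volume(mesh)
  if (abs(vol - volume_l / 1000) / (volume_l / 1000) > 0.05)
    stop(sprintf("mesh volume %.3g L misses nominal %.3g L by more than 5%%",
                 vol * 1000, volume_l), call. = FALSE)
  axis <- if (type == "v") c(0, 1, 0) else c(1, 0, 0)
  w <- wall(mesh, axis_point = attr(mesh, "pivot"), axis_dir = axis,
            rpm = rpm)
  attr(w, "nominal_volume_l") <- volume_l
  attr(w, "type") <- type
  w
}

# allocate per-component particle counts so realized mass fractions match
# the recipe; monodisperse-by-component d50 radii keep the count audit exact
.recipe_counts <- function(formulation, materials, budget) {
  comp <- formulation$components
  r50 <- vapply(materials[names(comp)], function(m)
    m$d50 * m$size_scale * 1e-6 / 2, numeric(1))
  rho <- vapply(materials[names(comp)], function(m)
    m$true_density * 1000, numeric(1))
  m1 <- rho * (4 / 3) * pi * r50^3          # mass of one d50 particle
  counts <- comp / m1
  counts <- round(counts / sum(counts) * budget)
  counts[counts < 1] <- 1
  realized <- counts * m1 / sum(counts * m1)
  dev <- max(abs(realized - comp))
  if (dev > 0.01)
    stop(sprintf(paste0("particle budget %d cannot honour the recipe: max ",
                        "mass-fraction deviation %.3f (raise the budget)"),
         budget, dev), call. = FALSE)
  counts
}

#' Fill a blender with a formulation
#'
#' Rain-fills the requested fill fraction of the blender volume with
#' particles whose per-component counts reproduce the recipe's mass
#' fractions (within 1%), then settles them under gravity.  Components are
#' layered in recipe order (the segregated initial state of a real charge);
#' `premixed = TRUE` interleaves them randomly instead.
#'
#' @param blender a [build_blender()] wall.
#' @param formulation a [formulation()].
#' @param materials named list of [material_params()] covering every
#'   component.
#' @param fill_fraction fraction of nominal volume to fill (0-1).
#' @param budget total particle budget.
#' @param seed RNG seed.
#' @param premixed interleave components randomly instead of layering.
#' @param settle_time settling cap (s).
#' @return a [particle_system()]; attribute `"bed_volume_target"` records
#'   `fill_fraction x nominal volume` (m^3).
#' @export
fill_blender <- function(blender, formulation, materials, fill_fraction,
                         budget = 3000, seed = 1, premixed = FALSE,
                         settle_time = 1.5) {
  if (fill_fraction <= 0 || fill_fraction >= 1)
    stop("fill_fraction must lie in (0, 1)", call. = FALSE)
  set.seed(seed)
  counts <- .recipe_counts(formulation, materials, budget)
  mats <- materials[names(counts)]
  mat_idx <- rep(seq_along(counts), counts)
  radius <- unlist(lapply(seq_along(counts), function(i)
    rep(mats[[i]]$d50 * mats[[i]]$size_scale * 1e-6 / 2, counts[i])))
  if (premixed) {
    ord <- sample.int(length(mat_idx))
    mat_idx <- mat_idx[ord]; radius <- radius[ord]
  }
  # seed positions on a lattice inside the mesh, bottom-up
  mesh <- blender$mesh
  s <- 2.1 * max(radius)
  bb_lo <- apply(mesh$vertices, 2, min) + s / 2
  bb_hi <- apply(mesh$vertices, 2, max) - s / 2
  g <- expand.grid(x = seq(bb_lo[1], bb_hi[1], by = s),
                   y = seq(bb_lo[2], bb_hi[2], by = s),
                   z = seq(bb_lo[3], bb_hi[3], by = s))
  g <- as.matrix(g)
  ok <- mesh$inside(g, margin = 1.2 * max(radius))
  g <- g[ok, , drop = FALSE]
  g <- g[order(g[, 3], g[, 1], g[, 2]), , drop = FALSE]
  n <- length(mat_idx)
  if (nrow(g) < n)
    stop("blender cannot hold the particle budget at this size scale",
         call. = FALSE)
  pos <- g[seq_len(n), , drop = FALSE]
  pos <- pos + matrix(runif(3 * n, -0.05, 0.05) * s, ncol = 3)
  sys <- particle_system(pos, radius, mat_idx, mats)
  target_bed <- fill_fraction * attr(blender, "nominal_volume_l") / 1000
  static_wall <- wall(mesh, axis_point = blender$axis_point,
                      axis_dir = blender$axis_dir, rpm = 0)
  sys <- .settle(sys, list(static_wall), max_time = settle_time)
  attr(sys, "bed_volume_target") <- target_bed
  attr(sys, "formulation") <- formulation
  sys
}

#' Realized bed volume of a settled particle system
#'
#' Solid volume divided by a random-close-packing fraction.
#'
#' @param system a [particle_system()].
#' @param packing assumed packing fraction (default 0.58).
#' @export
bed_volume <- function(system, packing = 0.58) {
  sum(4 / 3 * pi * system$radius^3) / packing
}

#' Audit realized mass fractions against a recipe
#'
#' @param system a [particle_system()].
#' @param formulation a [formulation()].
#' @return data frame with component, target and realized fractions and
#'   deviation.
#' @export
recipe_audit <- function(system, formulation) {
  mass_by <- tapply(system$mass, names(system$materials)[system$material],
                    sum)
  realized <- as.numeric(mass_by[names(formulation$components)]) /
    sum(system$mass)
  data.frame(component = names(formulation$components),
             target = as.numeric(formulation$components),
             realized = realized,
             deviation = realized - as.numeric(formulation$components),
             row.names = NULL)
}

#' Run a blending simulation
#'
#' Rotates the blender at its configured speed for `duration` seconds,
#' saving snapshots at the save interval.
#'
#' @param system a filled [particle_system()] (see [fill_blender()]).
#' @param blender the [build_blender()] wall.
#' @param duration simulated blending time (s).
#' @param save_interval snapshot spacing (s).
#' @param ... forwarded to [dem_run()].
#' @return a [dem_run()] result.
#' @export
run_blending <- function(system, blender, duration, save_interval, ...) {
  dem_run(system, list(blender), duration = duration,
          save_interval = save_interval, ...)
}

#' Default 8-bin sampling layout
#'
#' Eight equal sampling cylinders in a planar 4 x 2 grid spanning the bed's
#' horizontal extent, axes vertical, sized as fractions of the bed depth.
#'
#' @param x n x 3 particle positions of the sampled snapshot (m).
#' @param radius_frac bin radius as a fraction of the grid pitch.
#' @param height_frac bin height as a fraction of the bed depth.
#' @return data frame of 8 rows: `cx, cy, cz, radius, height`.
#' @export
sampling_bins <- function(x, radius_frac = 0.5, height_frac = 0.9) {
  # centre the 4 x 2 grid on position quantiles so every bin straddles
  # powder even when the bed is mid-cascade
  xc <- unname(stats::quantile(x[, 1], c(0.125, 0.375, 0.625, 0.875)))
  yc <- unname(stats::quantile(x[, 2], c(0.3, 0.7)))
  g <- expand.grid(cx = xc, cy = yc)
  pitch <- min(min(diff(xc)), max(diff(yc), diff(range(x[, 2])) / 4))
  cz <- numeric(nrow(g)); hh <- numeric(nrow(g))
  rad <- radius_frac * pitch
  for (b in seq_len(nrow(g))) {
    near <- (x[, 1] - g$cx[b])^2 + (x[, 2] - g$cy[b])^2 < (2 * rad)^2
    zs <- if (any(near)) x[near, 3] else x[, 3]
    cz[b] <- stats::median(zs)
    hh[b] <- height_frac * max(diff(stats::quantile(zs, c(0.05, 0.95))),
                               1e-6)
  }
  data.frame(cx = g$cx, cy = g$cy, cz = cz, radius = rad, height = hh)
}

#' Per-bin composition of a snapshot
#'
#' Assigns particles to vertical sampling cylinders and reports, per bin,
#' the API mass, total mass and drug content (bin API mass fraction over
#' the nominal API fraction, x 100, so a perfect mix reads 100%).
#'
#' @param x n x 3 positions (m).
#' @param system the [particle_system()] (for masses and materials).
#' @param bins bin table from [sampling_bins()] (or same columns).
#' @param formulation a [formulation()].
#' @param min_bins minimum non-empty bins required (default 4).
#' @return data frame per bin: `bin, n, api_mass, total_mass,
#'   drug_content`; empty bins are dropped with a warning.
#' @export
sample_bins <- function(x, system, bins, formulation, min_bins = 4) {
  api_idx <- match(formulation$api, names(system$materials))
  out <- lapply(seq_len(nrow(bins)), function(b) {
    bb <- bins[b, ]
    inside <- (x[, 1] - bb$cx)^2 + (x[, 2] - bb$cy)^2 < bb$radius^2 &
      abs(x[, 3] - bb$cz) < bb$height / 2
    tot <- sum(system$mass[inside])
    api <- sum(system$mass[inside & system$material == api_idx])
    data.frame(bin = b, n = sum(inside), api_mass = api, total_mass = tot,
               drug_content = if (tot > 0)
                 (api / tot) / formulation$nominal_api_fraction * 100
               else NA_real_)
  })
  out <- do.call(rbind, out)
  empty <- is.na(out$drug_content)
  if (any(empty)) {
    warning(sum(empty), " empty sampling bin(s) excluded", call. = FALSE)
    out <- out[!empty, , drop = FALSE]
  }
  if (nrow(out) < min_bins)
    stop("fewer than ", min_bins, " non-empty sampling bins", call. = FALSE)
  out
}

#' Content uniformity (%RSD)
#'
#' `100 x sample SD / mean` of per-bin drug contents.
#'
#' @param contents numeric vector of per-bin drug contents (>= 2 values).
#' @return percent RSD; `NA` when the mean is zero.
#' @export
content_uniformity <- function(contents) {
  if (length(contents) < 2)
    stop("need at least two bins for content uniformity", call. = FALSE)
  m <- mean(contents)
  if (m == 0) return(NA_real_)
  100 * sd(contents) / m
}

#' Blending metrics over a T-index series
#'
#' Evaluates per-bin drug content and content uniformity at T-index
#' instants T_i = 1, 2, ... (snapshots nearest `i x interval`), and reports
#' the first T_i whose metrics satisfy the specification (drug content
#' within `content_limits`, CU at most `cu_limit`).
#'
#' @param result a [run_blending()] result.
#' @param system the originating [particle_system()].
#' @param formulation a [formulation()].
#' @param interval T-index spacing in seconds; defaults to a seventh of the
#'   run, giving T_i = 1..7.
#' @param bins optional fixed bin table; defaults to [sampling_bins()] on
#'   each snapshot's bed.
#' @param blender optional [build_blender()] wall; when given, snapshots
#'   are rotated back to the blender's home orientation before binning
#'   (sampling fixed in the bed frame), which keeps the bin grid on the
#'   bed at every sampling instant.
#' @param content_limits acceptance band for mean drug content (%).
#' @param cu_limit acceptance cap for CU (%).
#' @return list with `metrics` (data frame: `t_index, time, mean_content,
#'   cu, meets_spec`), `per_bin` (list of bin tables) and
#'   `t_index_met` (first passing T_i, or `NA` if never).
#' @export
t_index_series <- function(result, system, formulation, interval = NULL,
                           bins = NULL, blender = NULL,
                           content_limits = c(95, 105), cu_limit = 5) {
  times <- result$times
  span <- max(times)
  if (is.null(interval)) interval <- span / 7
  ti_times <- seq_len(max(1L, round(span / interval))) * interval
  rows <- NULL; per_bin <- list()
  for (i in seq_along(ti_times)) {
    k <- which.min(abs(times - ti_times[i]))
    X <- result$X[[k]]
    if (!is.null(blender) && blender$omega != 0)
      X <- .derotate(X, blender, times[k])
    b <- if (is.null(bins)) sampling_bins(X) else bins
    sb <- sample_bins(X, system, b, formulation)
    cu <- content_uniformity(sb$drug_content)
    mc <- mean(sb$drug_content)
    rows <- rbind(rows, data.frame(
      t_index = i, time = times[k], mean_content = mc, cu = cu,
      meets_spec = mc >= content_limits[1] & mc <= content_limits[2] &
        cu <= cu_limit))
    per_bin[[i]] <- sb
  }
  met <- rows$t_index[rows$meets_spec]
  list(metrics = rows, per_bin = per_bin,
       t_index_met = if (length(met)) met[1] else NA_integer_)
}

#' @rdname t_index_series
#' @param metrics the `metrics` element of a [t_index_series()] result.
#' @param path CSV path.
#' @export
write_blend_metrics <- function(metrics, path) {
  write.csv(metrics, path, row.names = FALSE)
  invisible(metrics)
}

#' Regression comparison of simulated and experimental metric series
#'
#' Ordinary least squares of the experimental values on the simulated
#' values, with the summary statistics used to judge model transferability:
#' residual standard deviation S, R^2, adjusted R^2 and the slope p value.
#'
#' @param simulated,experimental equal-length numeric series (>= 3 points
#'   after dropping).
#' @param drop_first number of initial points to drop (early blending
#'   states carry large variability; default 0).
#' @return list with `slope`, `intercept`, `s`, `r_squared`,
#'   `adj_r_squared`, `p_value`, `n`.
#' @export
compare_series <- function(simulated, experimental, drop_first = 0) {
  if (length(simulated) != length(experimental))
    stop("series must have equal length", call. = FALSE)
  if (drop_first > 0) {
    simulated <- simulated[-seq_len(drop_first)]
    experimental <- experimental[-seq_len(drop_first)]
  }
  if (length(simulated) < 3)
    stop("need at least three paired points", call. = FALSE)
  if (sd(simulated) == 0)
    stop("zero variance in the simulated series: slope undefined",
         call. = FALSE)
  fit <- lm(experimental ~ simulated)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       s = sm$sigma, r_squared = sm$r.squared,
       adj_r_squared = sm$adj.r.squared,
       p_value = unname(sm$coefficients[2, 4]), n = length(simulated))
}


# rotate a snapshot back by the wall's rotation angle at time t (bed frame)
.derotate <- function(x, wall, t) {
  th <- -wall$omega * t
  u <- wall$axis_dir
  p <- sweep(x, 2, wall$axis_point)
  cth <- cos(th); sth <- sin(th)
  crossu <- cbind(u[2] * p[, 3] - u[3] * p[, 2],
                  u[3] * p[, 1] - u[1] * p[, 3],
                  u[1] * p[, 2] - u[2] * p[, 1])
  du <- drop(p %*% u)
  rot <- p * cth + crossu * sth + outer(du * (1 - cth), u)
  sweep(rot, 2, wall$axis_point, "+")
}
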