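# Monte-Carlo conversion of a deterministic design space into a robust
# operating space: factor setpoints are perturbed around each grid cell and
# the fraction of draws violating any specification limit is the cell's
# failure probability.

#' Perturbation model for operating-space Monte Carlo
#'
#' Factor settings are drawn from independent normals around the setpoint,
#' truncated to the factor ranges; optionally each response prediction also
#' receives residual noise with SD equal to the fit's residual SD (without
#' it, strictly interior setpoints can never fail).
#'
#' @param sd named numeric vector of per-factor setpoint SDs in natural
#'   units; factors not named get `default_frac` of their half-range.
#' @param default_frac default SD as a fraction of each factor's half-range
#'   (default 0.05).
#' @param residual_noise add response residual noise (default `TRUE`).
#' @param draws Monte-Carlo draws per evaluation (default 10000).
#' @param truncate truncate perturbed settings to the factor ranges
#'   (default `TRUE`; disable for unbounded analytic comparisons).
#' @return object of class `perturbation_model`.
#' @export
perturbation_model <- function(sd = NULL, default_frac = 0.05,
                               residual_noise = TRUE, draws = 10000,
                               truncate = TRUE) {
  if (!is.null(sd) && any(sd < 0)) stop("SDs must be >= 0", call. = FALSE)
  if (draws < 1) stop("'draws' must be >= 1", call. = FALSE)
  structure(list(sd = sd, default_frac = default_frac,
                 residual_noise = residual_noise, draws = as.integer(draws),
                 truncate = truncate),
            class = "perturbation_model")
}

.factor_sds <- function(factors, pm) {
  nms <- vapply(factors, `[[`, "", "name")
  sds <- vapply(seq_along(factors), function(i) {
    f <- factors[[i]]
    if (!is.null(pm$sd) && f$name %in% names(pm$sd)) pm$sd[[f$name]]
    else pm$default_frac * f$half_width
  }, numeric(1))
  setNames(sds, nms)
}

#' Monte-Carlo failure probability at a setpoint
#'
#' Draws perturbed factor settings, predicts every response, optionally
#' adds residual noise, and counts draws that violate any specification
#' limit.
#'
#' @param fits named list of [fit_rsm()] objects.
#' @param specs named list of [spec_limits()], names matching `fits`.
#' @param setpoint named list/data frame of natural-unit settings.
#' @param perturbation a [perturbation_model()].
#' @param seed integer seed (reproducible surfaces).
#' @return list with `probability`, `se` (binomial), `draws`.
#' @export
failure_probability <- function(fits, specs, setpoint,
                                perturbation = perturbation_model(),
                                seed = 1L) {
  .check_specs(fits, specs)
  factors <- fits[[1]]$factors
  if (!is.data.frame(setpoint)) setpoint <- as.data.frame(as.list(setpoint))
  set.seed(seed)
  p <- .failure_prob_one(fits, specs, factors, setpoint, perturbation)
  n <- perturbation$draws
  list(probability = p, se = sqrt(p * (1 - p) / n), draws = n)
}

# Shared worker: one setpoint, RNG state managed by the caller.
.failure_prob_one <- function(fits, specs, factors, setpoint, pm) {
  n <- pm$draws
  sds <- .factor_sds(factors, pm)
  draws <- lapply(seq_along(factors), function(i) {
    f <- factors[[i]]
    x <- rnorm(n, mean = setpoint[[f$name]], sd = sds[i])
    if (isTRUE(pm$truncate)) pmin(pmax(x, f$low), f$high) else x
  })
  draws <- as.data.frame(draws, col.names = names(sds))
  fail <- rep(FALSE, n)
  for (resp in names(specs)) {
    sp <- specs[[resp]]
    pr <- predict(fits[[resp]], draws)
    if (pm$residual_noise) {
      sig <- sqrt(fits[[resp]]$sigma2)
      if (is.finite(sig) && sig > 0) pr <- pr + rnorm(n, 0, sig)
    }
    fail <- fail | pr < sp$lower | pr > sp$upper
  }
  mean(fail)
}

#' Map an operating space over a factor grid
#'
#' Computes the Monte-Carlo failure probability for every grid cell and
#' flags cells below the cutoff as the robust operating region.  With zero
#' perturbation SDs and residual noise off the operating region equals the
#' deterministic design space exactly.
#'
#' @inheritParams failure_probability
#' @param grid,fixed factor grid and pins as in [design_space()].
#' @param alpha failure-probability cutoff (default 0.01, i.e. the <1%
#'   convention).
#' @return data frame of grid settings with `failure_probability`,
#'   `se`, and logical `operating` columns.
#' @export
operating_space_map <- function(fits, specs, grid = NULL, fixed = NULL,
                                perturbation = perturbation_model(),
                                alpha = 0.01, seed = 1L) {
  .check_specs(fits, specs)
  factors <- fits[[1]]$factors
  g <- .expand_grid(factors, grid, fixed)
  set.seed(seed)
  probs <- vapply(seq_len(nrow(g)), function(i)
    .failure_prob_one(fits, specs, factors, g[i, , drop = FALSE],
                      perturbation),
    numeric(1))
  g$failure_probability <- probs
  g$se <- sqrt(probs * (1 - probs) / perturbation$draws)
  g$operating <- if (alpha >= 1) rep(TRUE, nrow(g)) else probs < alpha
  g
}

#' Write an operating-space probability surface to CSV
#'
#' @param map result of [operating_space_map()].
#' @param path CSV path.
#' @export
write_operating_space <- function(map, path) {
  write.csv(map, path, row.names = FALSE)
  invisible(map)
}
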