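# Box-Behnken response-surface modelling on coded factors.
#
# Factors are coded to [-1, 1] as (natural - center) / half-width, so that
# the low level maps to -1, the center to 0 and the high level to +1.  All
# fits are ordinary least squares on the coded scale; on the orthogonal
# Box-Behnken design the partial (type-III) term sums of squares equal the
# sequential ones.

#' Define a DoE factor
#'
#' @param name factor name.
#' @param low,high natural-unit levels coded to -1 and +1.
#' @param center natural-unit center; defaults to the midpoint.
#' @return an object of class `factor_def`.
#' @examples
#' factor_def("filling_level", 30, 70)  # center 50, half-width 20
#' @export
factor_def <- function(name, low, high, center = (low + high) / 2) {
  if (!is.character(name) || length(name) != 1L)
    stop("'name' must be a single string", call. = FALSE)
  if (!(low < center && center < high))
    stop(sprintf("factor '%s' needs low < center < high", name), call. = FALSE)
  structure(list(name = name, low = low, high = high, center = center,
                 half_width = (high - low) / 2),
            class = "factor_def")
}

.check_factors <- function(factors) {
  if (!is.list(factors) || !all(vapply(factors, inherits, TRUE, "factor_def")))
    stop("'factors' must be a list of factor_def objects", call. = FALSE)
  factors
}

#' Code natural factor settings to the [-1, 1] scale
#'
#' @param settings data frame (or named list/vector) of natural-unit
#'   settings, one column per factor.
#' @param factors list of [factor_def()] objects.
#' @param warn_extrapolation warn when a coded value falls outside
#'   \[-1, 1\] (allowed, flagged).
#' @return data frame of coded settings named `x1`, `x2`, ... in factor
#'   order.
#' @export
code_factors <- function(settings, factors, warn_extrapolation = TRUE) {
  factors <- .check_factors(factors)
  if (!is.data.frame(settings)) settings <- as.data.frame(as.list(settings))
  coded <- lapply(seq_along(factors), function(i) {
    f <- factors[[i]]
    if (!f$name %in% names(settings))
      stop(sprintf("settings lack factor '%s'", f$name), call. = FALSE)
    (settings[[f$name]] - f$center) / f$half_width
  })
  coded <- as.data.frame(coded, col.names = paste0("x", seq_along(factors)))
  if (warn_extrapolation && any(abs(as.matrix(coded)) > 1 + 1e-9))
    warning("coded settings fall outside [-1, 1] (extrapolation)", call. = FALSE)
  coded
}

#' @rdname code_factors
#' @param coded data frame of coded settings (`x1`, `x2`, ...).
#' @return `decode_factors()` returns natural-unit settings.
#' @export
decode_factors <- function(coded, factors) {
  factors <- .check_factors(factors)
  out <- lapply(seq_along(factors), function(i)
    coded[[paste0("x", i)]] * factors[[i]]$half_width + factors[[i]]$center)
  as.data.frame(out, col.names = vapply(factors, `[[`, "", "name"))
}

# Canonical 3-factor Box-Behnken coded rows: the 12 edge midpoints of the
# factor cube (exactly one zero per run).
.BBD3 <- as.data.frame(matrix(c(
  -1, -1,  0,
   1, -1,  0,
  -1,  1,  0,
   1,  1,  0,
  -1,  0, -1,
   1,  0, -1,
  -1,  0,  1,
   1,  0,  1,
   0, -1, -1,
   0,  1, -1,
   0, -1,  1,
   0,  1,  1), ncol = 3, byrow = TRUE,
  dimnames = list(NULL, c("x1", "x2", "x3"))))

#' Build a 3-factor Box-Behnken design
#'
#' Returns the 12 edge-midpoint runs plus replicated center runs, with run
#' order shuffled by `seed`.  Coded settings use \{-1, 0, +1\}.
#'
#' @param factors list of exactly three [factor_def()] objects.
#' @param center_runs number of replicated center points (default 3).
#' @param seed integer seed for the run-order shuffle; `NULL` keeps the
#'   canonical order.
#' @return data frame with columns `run`, the natural-unit factor columns,
#'   and coded `x1`, `x2`, `x3`; the factor list is attached as attribute
#'   `"factors"`.
#' @export
build_bbd <- function(factors, center_runs = 3, seed = NULL) {
  factors <- .check_factors(factors)
  if (length(factors) != 3L)
    stop("Box-Behnken construction here supports exactly 3 factors",
         call. = FALSE)
  coded <- .BBD3
  if (center_runs > 0)
    coded <- rbind(coded, as.data.frame(matrix(0, center_runs, 3,
                   dimnames = list(NULL, c("x1", "x2", "x3")))))
  if (!is.null(seed)) {
    ord <- local({ set.seed(seed); sample.int(nrow(coded)) })
    coded <- coded[ord, , drop = FALSE]
  }
  rownames(coded) <- NULL
  nat <- decode_factors(coded, factors)
  out <- cbind(run = seq_len(nrow(coded)), nat, coded)
  attr(out, "factors") <- factors
  out
}

# Model-matrix column for one term on a coded design; terms are strings in
# {x1, x2, x3, x1x2, x1x3, x2x3, x1^2, x2^2, x3^2}.
.term_column <- function(term, coded) {
  if (grepl("^x[0-9]+$", term)) return(coded[[term]])
  if (grepl("^x[0-9]+\\^2$", term)) {
    v <- coded[[sub("\\^2$", "", term)]]
    return(v * v)
  }
  m <- regmatches(term, regexec("^(x[0-9]+)(x[0-9]+)$", term))[[1]]
  if (length(m) == 3L) return(coded[[m[2]]] * coded[[m[3]]])
  stop(sprintf("unrecognised model term '%s'", term), call. = FALSE)
}

.model_matrix <- function(terms, coded) {
  cols <- lapply(terms, .term_column, coded = coded)
  X <- cbind(intercept = 1, do.call(cbind, cols))
  colnames(X) <- c("intercept", terms)
  X
}

#' Fit a reduced response-surface model on coded factors
#'
#' Ordinary least squares of a response on a caller-specified subset of the
#' quadratic polynomial terms, using the coded (-1..+1) factor scale.
#' Optionally performs backward elimination of terms with p above a cutoff.
#'
#' @param runs design/response table in natural units (e.g. from
#'   [build_bbd()] or a CSV of experimental runs).
#' @param response name of the response column in `runs`.
#' @param factors list of [factor_def()]; defaults to the `"factors"`
#'   attribute of `runs`.
#' @param terms character vector of model terms, e.g.
#'   `c("x1","x2","x3","x1x2","x2x3")`.  The intercept is always included.
#' @param backward_alpha if non-`NULL`, repeatedly drop the least
#'   significant term with p > `backward_alpha`.
#' @return object of class `rsm_fit` with coefficients (coded scale),
#'   residuals, and the ingredients for [anova_rsm()] and
#'   [predict.rsm_fit()].
#' @export
fit_rsm <- function(runs, response, factors = attr(runs, "factors"),
                    terms = c("x1", "x2", "x3"), backward_alpha = NULL) {
  factors <- .check_factors(factors)
  if (!response %in% names(runs))
    stop(sprintf("response '%s' not found in runs", response), call. = FALSE)
  y <- runs[[response]]
  if (anyNA(y)) stop("response contains missing values", call. = FALSE)
  nat_names <- vapply(factors, `[[`, "", "name")
  coded <- code_factors(runs[, nat_names, drop = FALSE], factors,
                        warn_extrapolation = FALSE)
  repeat {
    X <- .model_matrix(terms, coded)
    if (nrow(X) < ncol(X))
      stop("fewer runs than model terms", call. = FALSE)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      stop("singular design: aliased term(s) ",
           paste(aliased, collapse = ", "), call. = FALSE)
    }
    beta <- qr.coef(qrX, y)
    fitted <- drop(X %*% beta)
    res <- y - fitted
    df_res <- nrow(X) - ncol(X)
    sigma2 <- if (df_res > 0) sum(res^2) / df_res else NA_real_
    XtXinv <- chol2inv(qr.R(qrX))
    se <- sqrt(diag(XtXinv) * sigma2)
    tval <- beta / se
    pval <- 2 * pt(abs(tval), df_res, lower.tail = FALSE)
    if (is.null(backward_alpha) || length(terms) == 0L) break
    cand <- pval[-1]                       # never drop the intercept
    if (all(cand <= backward_alpha, na.rm = TRUE)) break
    terms <- terms[-which.max(cand)]
  }
  structure(list(response = response, terms = terms, coefficients = beta,
                 se = se, t = tval, p = pval, residuals = res,
                 fitted = fitted, y = y, X = X, XtXinv = XtXinv,
                 df_residual = df_res, sigma2 = sigma2,
                 factors = factors, coded = coded),
            class = "rsm_fit")
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat(sprintf("Coded response-surface fit: %s ~ %s\n", x$response,
              paste(x$terms, collapse = " + ")))
  print(round(x$coefficients, 4))
  a <- anova_rsm(x)
  cat(sprintf("R2 %.4f  adj %.4f  pred %.4f  (F = %.2f on %d, %d DF)\n",
              a$r_squared, a$adj_r_squared, a$pred_r_squared,
              a$F, a$df_model, a$df_residual))
  invisible(x)
}

#' ANOVA for a response-surface fit
#'
#' Partitions the corrected total sum of squares into model and residual,
#' reports per-term partial sums of squares (equal to sequential on the
#' orthogonal Box-Behnken design), the model F statistic and p value, and
#' the R-squared family.  Predicted R-squared uses the PRESS statistic from
#' leave-one-out leverages.
#'
#' @param fit an [fit_rsm()] object.
#' @return list with `table` (per-source data frame), `ss_model`,
#'   `ss_residual`, `ss_total`, `df_model`, `df_residual`, `F`, `p`,
#'   `r_squared`, `adj_r_squared`, `pred_r_squared`, `press`.
#' @export
anova_rsm <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  y <- fit$y
  n <- length(y)
  ss_total <- sum((y - mean(y))^2)
  ss_res <- sum(fit$residuals^2)
  ss_model <- ss_total - ss_res
  df_model <- length(fit$terms)
  df_res <- fit$df_residual
  ms_model <- ss_model / df_model
  ms_res <- if (df_res > 0) ss_res / df_res else NA_real_
  Fval <- ms_model / ms_res
  pval <- if (df_res > 0) pf(Fval, df_model, df_res, lower.tail = FALSE)
          else NA_real_
  # partial SS of term j: beta_j^2 / [(X'X)^{-1}]_jj
  idx <- seq_along(fit$terms) + 1L
  ss_terms <- fit$coefficients[idx]^2 / diag(fit$XtXinv)[idx]
  F_terms <- ss_terms / ms_res
  p_terms <- if (df_res > 0) pf(F_terms, 1, df_res, lower.tail = FALSE)
             else rep(NA_real_, length(idx))
  # leverages and PRESS
  h <- rowSums((fit$X %*% fit$XtXinv) * fit$X)
  press <- sum((fit$residuals / (1 - h))^2)
  r2 <- ss_model / ss_total
  adj_r2 <- 1 - (ss_res / df_res) / (ss_total / (n - 1))
  pred_r2 <- 1 - press / ss_total
  tab <- data.frame(
    source = c("model", fit$terms, "residual", "total"),
    ss = c(ss_model, ss_terms, ss_res, ss_total),
    df = c(df_model, rep(1L, length(idx)), df_res, n - 1L),
    ms = c(ms_model, ss_terms, ms_res, NA),
    F = c(Fval, F_terms, NA, NA),
    p = c(pval, p_terms, NA, NA),
    row.names = NULL)
  list(table = tab, ss_model = ss_model, ss_residual = ss_res,
       ss_total = ss_total, df_model = df_model, df_residual = df_res,
       ms_model = ms_model, ms_residual = ms_res, F = Fval, p = pval,
       r_squared = r2, adj_r_squared = adj_r2, pred_r_squared = pred_r2,
       press = press)
}

#' Predict from a response-surface fit
#'
#' Evaluates the coded polynomial at natural-unit settings, with an
#' optional confidence interval for the mean response from the t
#' distribution on the residual degrees of freedom.
#'
#' @param object an [fit_rsm()] object.
#' @param newdata data frame of natural-unit settings (one column per
#'   factor name).
#' @param interval `"none"` or `"confidence"`.
#' @param level confidence level (default 0.95).
#' @param ... unused.
#' @return numeric vector of predictions, or a data frame with `fit`,
#'   `lwr`, `upr` when an interval is requested.
#' @export
predict.rsm_fit <- function(object, newdata, interval = c("none", "confidence"),
                            level = 0.95, ...) {
  interval <- match.arg(interval)
  coded <- code_factors(newdata, object$factors, warn_extrapolation = FALSE)
  X <- .model_matrix(object$terms, coded)
  pred <- drop(X %*% object$coefficients)
  if (interval == "none") return(pred)
  se_mean <- sqrt(rowSums((X %*% object$XtXinv) * X) * object$sigma2)
  tq <- qt(1 - (1 - level) / 2, object$df_residual)
  data.frame(fit = pred, lwr = pred - tq * se_mean, upr = pred + tq * se_mean)
}

#' Specification limits for a response
#'
#' @param lower,upper optional acceptance limits (at least one required).
#' @param target optimisation direction: `"maximize"`, `"minimize"` or
#'   `"inside"` (just satisfy the limits).
#' @return object of class `spec_limits`.
#' @export
spec_limits <- function(lower = -Inf, upper = Inf,
                        target = c("inside", "maximize", "minimize")) {
  target <- match.arg(target)
  if (!(lower < upper))
    stop("'lower' must be below 'upper'", call. = FALSE)
  structure(list(lower = lower, upper = upper, target = target),
            class = "spec_limits")
}

.check_specs <- function(fits, specs) {
  if (!is.list(fits) || !all(vapply(fits, inherits, TRUE, "rsm_fit")))
    stop("'fits' must be a named list of rsm_fit objects", call. = FALSE)
  if (is.null(names(specs)) || !all(names(specs) %in% names(fits)))
    stop("every spec must name a fitted response", call. = FALSE)
  invisible(TRUE)
}

# Expand a factor grid (named list of natural-unit vectors), applying pins.
.expand_grid <- function(factors, grid, fixed = NULL) {
  nms <- vapply(factors, `[[`, "", "name")
  axes <- lapply(nms, function(nm) {
    if (!is.null(fixed) && nm %in% names(fixed)) return(fixed[[nm]])
    if (!is.null(grid) && nm %in% names(grid)) return(grid[[nm]])
    f <- factors[[match(nm, nms)]]
    seq(f$low, f$high, length.out = 21)
  })
  names(axes) <- nms
  g <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  if (nrow(g) == 0L) stop("empty factor grid", call. = FALSE)
  g
}

#' Deterministic design space over a factor grid
#'
#' A grid cell is acceptable when every response's prediction (or, in
#' strict mode, its 95% confidence bound nearer the limit) satisfies that
#' response's specification limits.
#'
#' @param fits named list of [fit_rsm()] objects sharing the same factors.
#' @param specs named list of [spec_limits()], names matching `fits`.
#' @param grid named list of natural-unit axis vectors (missing factors get
#'   a 21-point sweep over their range).
#' @param fixed named list pinning factors to single values.
#' @param strict use the 95% confidence bound instead of the point
#'   prediction.
#' @param level confidence level for strict mode.
#' @return data frame of grid settings with per-response predictions and a
#'   logical `acceptable` column.
#' @export
design_space <- function(fits, specs, grid = NULL, fixed = NULL,
                         strict = FALSE, level = 0.95) {
  .check_specs(fits, specs)
  factors <- fits[[1]]$factors
  g <- .expand_grid(factors, grid, fixed)
  ok <- rep(TRUE, nrow(g))
  for (resp in names(specs)) {
    sp <- specs[[resp]]
    if (strict) {
      pr <- predict(fits[[resp]], g, interval = "confidence", level = level)
      g[[paste0("pred_", resp)]] <- pr$fit
      ok <- ok & pr$lwr >= sp$lower & pr$upr <= sp$upper
    } else {
      pr <- predict(fits[[resp]], g)
      g[[paste0("pred_", resp)]] <- pr
      ok <- ok & pr >= sp$lower & pr <= sp$upper
    }
  }
  g$acceptable <- ok
  g
}

#' Ranked feasible settings from a design space
#'
#' Grid search over the design space, scoring feasible settings by a
#' desirability built from each response's direction (`maximize`,
#' `minimize`, or distance-to-limits for `inside`) and ranking by the
#' geometric-mean desirability.  Ties are broken by lower filling level
#' (first factor), then higher speed (second factor).
#'
#' @inheritParams design_space
#' @return data frame of feasible settings sorted best-first with a
#'   `desirability` column; zero rows (with a message attribute) when the
#'   specs are infeasible on the grid.
#' @export
optimize_settings <- function(fits, specs, grid = NULL, fixed = NULL) {
  ds <- design_space(fits, specs, grid = grid, fixed = fixed)
  feas <- ds[ds$acceptable, , drop = FALSE]
  if (nrow(feas) == 0L) {
    attr(feas, "diagnostic") <- "no grid cell satisfies all specification limits"
    return(feas)
  }
  d_all <- rep(1, nrow(feas))
  for (resp in names(specs)) {
    sp <- specs[[resp]]
    pr <- feas[[paste0("pred_", resp)]]
    rng <- range(pr)
    span <- if (diff(rng) > 0) diff(rng) else 1
    d <- switch(sp$target,
      maximize = (pr - rng[1]) / span,
      minimize = (rng[2] - pr) / span,
      inside = 1 - abs(pr - (sp$lower + sp$upper) / 2) /
                 ((sp$upper - sp$lower) / 2))
    d_all <- d_all * pmax(d, 1e-12)
  }
  feas$desirability <- d_all^(1 / length(specs))
  nms <- vapply(fits[[1]]$factors, `[[`, "", "name")
  ord <- order(-feas$desirability, feas[[nms[1]]],
               if (length(nms) > 1) -feas[[nms[2]]] else NULL)
  feas <- feas[ord, , drop = FALSE]
  rownames(feas) <- NULL
  feas
}

#' Read a DoE run table from CSV
#'
#' One row per run, factor columns in natural units, response columns.
#'
#' @param path CSV path.
#' @param factors optional list of [factor_def()] attached as the
#'   `"factors"` attribute.
#' @export
read_runs <- function(path, factors = NULL) {
  runs <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(factors)) attr(runs, "factors") <- .check_factors(factors)
  runs
}

#' @rdname read_runs
#' @param runs run table to write.
#' @export
write_runs <- function(runs, path) {
  drop_cols <- grep("^x[0-9]+$", names(runs))
  out <- if (length(drop_cols)) runs[, -drop_cols, drop = FALSE] else runs
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}
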