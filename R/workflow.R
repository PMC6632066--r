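# Configuration-driven workflow tying the stages together:
# risk -> doe -> operating space -> blend demo, with a provenance manifest.

#' Load and validate a workflow configuration
#'
#' YAML schema (all paths relative to the config file unless absolute):
#' \preformatted{
#' seed: 1
#' out_dir: runs/demo
#' stages: [risk, doe, ospace, blend]
#' risk:
#'   register: path/to/register.csv     # omit to use the bundled table
#'   confidence: 0.9
#' doe:
#'   runs: path/to/runs.csv             # omit to use the bundled 15 runs
#'   responses:
#'     drug_content: {terms: [x1,x2,x3,x1x2,x2x3], lower: 95, upper: 105,
#'                    target: maximize}
#'     cu:           {terms: [x1,x2,x3,x1x3,x2x3], upper: 5,
#'                    target: minimize}
#'   pin: {blending_time: 24}
#' ospace:
#'   draws: 10000
#'   alpha: 0.01
#' blend:
#'   kind: v_blender
#'   budget: 1500
#'   rpm: 24
#'   duration: 5
#'   save_interval: 0.5
#' }
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return validated config list (class `run_config`).
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    base <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
    config$.base <- base
  } else config$.base <- getwd()
  known <- c("seed", "out_dir", "stages", "risk", "doe", "ospace", "blend",
             ".base")
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("unknown config field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$stages)) config$stages <- c("risk", "doe", "ospace")
  bad <- setdiff(config$stages, c("risk", "doe", "ospace", "blend"))
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(config$out_dir))
    stop("config field 'out_dir' is required", call. = FALSE)
  class(config) <- "run_config"
  config
}

.resolve_path <- function(path, base) {
  if (is.null(path)) NULL
  else if (grepl("^(/|[A-Za-z]:)", path)) path
  else file.path(base, path)
}

#' Run the configured workflow stages
#'
#' Executes the requested stages in dependency order (risk, DoE fits,
#' Monte-Carlo operating space, miniature blending demo), writes each
#' stage's artifacts under `out_dir`, and records a manifest with seeds,
#' input checksums and per-stage outputs.
#'
#' @param config a [read_run_config()] object, config path or list.
#' @return invisibly, a list of stage results plus the manifest.
#' @export
run_workflow <- function(config) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  out <- .resolve_path(config$out_dir, config$.base)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("blendsim")),
                   seed = config$seed, stages = config$stages,
                   inputs = list(), outputs = list())
  results <- list()
  fx <- study_fixtures()

  if ("risk" %in% config$stages) {
    path <- .resolve_path(config$risk$register, config$.base)
    reg <- if (is.null(path)) fx$register else read_risk_register(path)
    if (!is.null(path)) manifest$inputs$risk_register <- unname(tools::md5sum(path))
    conf <- if (is.null(config$risk$confidence)) 0.9 else config$risk$confidence
    scored <- score_risk_register(reg)
    pareto <- pareto_summary(scored, pareto_threshold(confidence = conf))
    f1 <- file.path(out, "risk_scored.csv")
    f2 <- file.path(out, "risk_pareto.csv")
    write_risk_register(reg, f1)
    write.csv(pareto, f2, row.names = FALSE)
    manifest$outputs$risk <- basename(c(f1, f2))
    results$risk <- list(scored = scored, pareto = pareto)
  }

  fits <- NULL; specs <- NULL
  if (any(c("doe", "ospace") %in% config$stages)) {
    path <- .resolve_path(config$doe$runs, config$.base)
    runs <- if (is.null(path)) fx$runs
            else read_runs(path, factors = blending_factors())
    if (!is.null(path)) manifest$inputs$doe_runs <- unname(tools::md5sum(path))
    responses <- config$doe$responses
    if (is.null(responses))
      responses <- list(
        drug_content = list(terms = c("x1", "x2", "x3", "x1x2", "x2x3"),
                            lower = 95, upper = 105, target = "maximize"),
        cu = list(terms = c("x1", "x2", "x3", "x1x3", "x2x3"),
                  upper = 5, target = "minimize"))
    fits <- lapply(names(responses), function(nm)
      fit_rsm(runs, nm, terms = unlist(responses[[nm]]$terms)))
    names(fits) <- names(responses)
    specs <- lapply(responses, function(rs)
      spec_limits(lower = if (is.null(rs$lower)) -Inf else rs$lower,
                  upper = if (is.null(rs$upper)) Inf else rs$upper,
                  target = if (is.null(rs$target)) "inside" else rs$target))
    coefs <- do.call(rbind, lapply(names(fits), function(nm)
      data.frame(response = nm, term = names(fits[[nm]]$coefficients),
                 coefficient = unname(fits[[nm]]$coefficients))))
    f <- file.path(out, "doe_coefficients.csv")
    write.csv(coefs, f, row.names = FALSE)
    manifest$outputs$doe <- basename(f)
    results$doe <- fits
  }

  if ("ospace" %in% config$stages) {
    pin <- config$doe$pin
    draws <- if (is.null(config$ospace$draws)) 10000 else config$ospace$draws
    alpha <- if (is.null(config$ospace$alpha)) 0.01 else config$ospace$alpha
    map <- operating_space_map(
      fits, specs, fixed = pin,
      perturbation = perturbation_model(draws = draws),
      alpha = alpha, seed = config$seed)
    f <- file.path(out, "operating_space.csv")
    write_operating_space(map, f)
    manifest$outputs$ospace <- basename(f)
    results$ospace <- map
  }

  if ("blend" %in% config$stages) {
    bc <- config$blend
    kind <- if (is.null(bc$kind)) "v_blender" else bc$kind
    budget <- if (is.null(bc$budget)) 1500 else bc$budget
    rpm <- if (is.null(bc$rpm)) 24 else bc$rpm
    duration <- if (is.null(bc$duration)) 5 else bc$duration
    si <- if (is.null(bc$save_interval)) duration / 7 else bc$save_interval
    scene <- mini_scene(kind, budget = budget, seed = config$seed, rpm = rpm)
    res <- run_blending(scene$system, scene$blender, duration, si)
    ti <- t_index_series(res, scene$system, scene$formulation)
    f <- file.path(out, "blend_metrics.csv")
    write_blend_metrics(ti$metrics, f)
    manifest$outputs$blend <- basename(f)
    results$blend <- ti
  }

  mf <- file.path(out, "manifest.yaml")
  yaml::write_yaml(manifest, mf)
  results$manifest <- manifest
  invisible(results)
}
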