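#' @useDynLib blendsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm coef predict pf pt qt rnorm runif sd setNames
#' @importFrom utils read.csv write.csv head
"_PACKAGE"

# FMEA scores are elicited on the odd five-point ladder used in
# pharmaceutical risk registers.
.FMEA_SCORES <- c(1L, 3L, 5L, 7L, 9L)

#' Risk priority number
#'
#' Computes the FMEA risk priority number as the product of severity,
#' probability of occurrence and detectability.  Each score is elicited on
#' the ladder 1, 3, 5, 7, 9 (1 = negligible impact / rare / always detected,
#' 9 = severe / frequent / undetectable), so the RPN ranges from 1 to 729.
#'
#' @param severity,occurrence,detectability integer scores, each in
#'   \{1, 3, 5, 7, 9\} (vectors recycled to common length).
#' @param permissive if `TRUE`, accept any integer score in 1..9 instead of
#'   the odd ladder.  Off by default.
#' @return integer vector of RPN values.
#' @examples
#' compute_rpn(7, 7, 7) # 343
#' @export
compute_rpn <- function(severity, occurrence, detectability, permissive = FALSE) {
  scores <- list(severity = severity, occurrence = occurrence,
                 detectability = detectability)
  for (nm in names(scores)) {
    s <- scores[[nm]]
    if (length(s) == 0L || anyNA(s))
      stop(sprintf("'%s' must be non-missing", nm), call. = FALSE)
    if (any(s != as.integer(s)))
      stop(sprintf("'%s' must be integer-valued", nm), call. = FALSE)
    ok <- if (permissive) s >= 1 & s <= 9 else s %in% .FMEA_SCORES
    if (!all(ok))
      stop(sprintf("'%s' contains score(s) outside the allowed set {1,3,5,7,9}: %s",
                   nm, paste(unique(s[!ok]), collapse = ", ")), call. = FALSE)
  }
  as.integer(severity * occurrence * detectability)
}

#' Classify an RPN into a risk level
#'
#' Cut-offs follow the three-band convention: `low` below 82, `medium` for
#' 82--245, `high` for 246 and above.
#'
#' @param rpn integer RPN in 1..729.
#' @return factor with levels `low < medium < high`.
#' @export
classify_risk <- function(rpn) {
  if (anyNA(rpn) || any(rpn < 1) || any(rpn > 729))
    stop("'rpn' must lie in 1..729", call. = FALSE)
  lev <- ifelse(rpn < 82, "low", ifelse(rpn <= 245, "medium", "high"))
  factor(lev, levels = c("low", "medium", "high"), ordered = TRUE)
}

#' Pareto threshold for RPN screening
#'
#' Threshold below which parameters are not carried forward, computed as
#' `max_rpn * (1 - confidence)`; with the full-scale maximum of 729 and 90%
#' confidence this gives 72.9.
#'
#' @param max_rpn maximum attainable RPN (default 729).
#' @param confidence screening confidence in \[0, 1\] (default 0.9).
#' @return numeric threshold.
#' @export
pareto_threshold <- function(max_rpn = 729, confidence = 0.9) {
  if (!is.numeric(confidence) || is.na(confidence) ||
      confidence < 0 || confidence > 1)
    stop("'confidence' must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(max_rpn) || is.na(max_rpn) || max_rpn <= 0)
    stop("'max_rpn' must be positive", call. = FALSE)
  max_rpn * (1 - confidence)
}

#' Score a risk register
#'
#' Adds `rpn` and `level` columns to a register of (parameter, attribute)
#' rows carrying S/P/D scores.
#'
#' @param register data frame with columns `parameter`, `attribute`,
#'   `S`, `P`, `D` and optionally `justification`.
#' @inheritParams compute_rpn
#' @return the register with `rpn` (integer) and `level` (ordered factor)
#'   appended.
#' @export
score_risk_register <- function(register, permissive = FALSE) {
  need <- c("parameter", "attribute", "S", "P", "D")
  missing_cols <- setdiff(need, names(register))
  if (length(missing_cols))
    stop("register is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  register$rpn <- compute_rpn(register$S, register$P, register$D,
                              permissive = permissive)
  register$level <- classify_risk(register$rpn)
  register
}

#' Pareto summary of a scored register
#'
#' Ranks attributes within each process parameter by RPN (descending, ties
#' kept in input order) and reports each entry's percentage of the
#' parameter's RPN total, the cumulative percentage, and whether the entry
#' exceeds the screening threshold.
#'
#' @param entries scored register (see [score_risk_register()]); must
#'   contain `parameter`, `attribute`, `rpn`.
#' @param threshold RPN screening threshold (default [pareto_threshold()]).
#' @return data frame with columns `parameter`, `attribute`, `rpn`,
#'   `pct`, `cum_pct`, `above_threshold`, ordered by parameter then
#'   descending RPN.
#' @export
pareto_summary <- function(entries, threshold = pareto_threshold()) {
  if (is.null(entries) || nrow(entries) == 0L)
    stop("'entries' must contain at least one row", call. = FALSE)
  if (!all(c("parameter", "attribute", "rpn") %in% names(entries)))
    stop("'entries' must have columns parameter, attribute, rpn", call. = FALSE)
  parts <- split(entries, factor(entries$parameter,
                                 levels = unique(entries$parameter)))
  out <- lapply(parts, function(df) {
    ord <- order(-df$rpn)            # base order() is stable: ties keep input order
    df <- df[ord, , drop = FALSE]
    tot <- sum(df$rpn)
    pct <- 100 * df$rpn / tot
    data.frame(parameter = df$parameter, attribute = df$attribute,
               rpn = df$rpn, pct = pct, cum_pct = cumsum(pct),
               above_threshold = df$rpn > threshold,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read / write a risk-register CSV
#'
#' The on-disk schema is `parameter, attribute, S, P, D, justification`;
#' the writer appends the computed `rpn` and `level` columns.
#'
#' @param path CSV path.
#' @return `read_risk_register()` returns the (unscored) register.
#' @export
read_risk_register <- function(path) {
  reg <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("parameter", "attribute", "S", "P", "D")
  missing_cols <- setdiff(need, names(reg))
  if (length(missing_cols))
    stop("risk register CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  reg
}

#' @rdname read_risk_register
#' @param register register to score and write.
#' @export
write_risk_register <- function(register, path) {
  scored <- score_risk_register(register)
  scored$level <- as.character(scored$level)
  write.csv(scored, path, row.names = FALSE)
  invisible(scored)
}
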