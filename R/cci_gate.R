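# Age-adjusted Charlson Comorbidity Index, ten-year survival transform and
# the pipeline's two hard gates (age limit and life expectancy).

#' Default Charlson weight table
#'
#' Loads the original Charlson weights (1/2/3/6 tiers) from the packaged
#' YAML config. The table is data, not code: users may substitute an
#' alternative weight set (e.g. an updated comorbidity calculator) by
#' passing their own file.
#'
#' @param path Optional path to a weight-table YAML; defaults to the
#'   packaged table.
#' @return A list with elements \code{weights} (named numeric vector) and
#'   \code{supersedes} (named character vector mapping a severe condition to
#'   the milder form of the same organ system that it supersedes).
#' @export
charlson_weights <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "charlson_weights.yaml", package = "psarag")
  }
  cfg <- yaml::read_yaml(path)
  w <- unlist(cfg$weights)
  storage.mode(w) <- "double"
  list(weights = w, supersedes = unlist(cfg$supersedes) %||% character())
}

config_error <- function(msg) {
  stop(errorCondition(msg, class = c("psarag_config_error", "psarag_error")))
}

domain_error <- function(msg) {
  stop(errorCondition(msg, class = c("psarag_domain_error", "psarag_error")))
}

#' Age points for the age-adjusted Charlson index
#'
#' One point per decade from age 50: 50-59 scores 1, 60-69 scores 2, 70-79
#' scores 3, 80 and above scores 4; below 50 scores 0.
#'
#' @param age Age in years.
#' @return Integer age points.
#' @export
cci_age_points <- function(age) {
  as.integer(pmin(pmax(age %/% 10L - 4L, 0L), 4L))
}

#' Charlson Comorbidity Index for a case
#'
#' Sums the published weights of the conditions present (each condition
#' counted once; when both a mild and a severe form of the same organ system
#' are coded — e.g. uncomplicated diabetes alongside diabetes with end-organ
#' damage — only the severe weight counts) and adds age points per decade
#' band.
#'
#' @param case A \code{case_scenario}.
#' @param weights Weight table from \code{\link{charlson_weights}}.
#' @return Object of class \code{cci_result}: \code{comorbidity_points},
#'   \code{age_points}, \code{score}, \code{ten_year_survival} and an
#'   \code{itemized} data frame of (condition, weight) pairs.
#' @export
cci_score <- function(case, weights = charlson_weights()) {
  stopifnot(inherits(case, "case_scenario"))
  conds <- setdiff(case$comorbidities, "none")
  missing_w <- setdiff(conds, names(weights$weights))
  if (length(missing_w)) {
    config_error(sprintf("weight table lacks condition(s): %s",
                         paste(missing_w, collapse = ", ")))
  }
  # drop the milder form when its severe counterpart is also coded
  sup <- weights$supersedes
  dropped <- unname(sup[names(sup) %in% conds])
  conds <- setdiff(conds, dropped)
  itemized <- data.frame(condition = conds,
                         weight = unname(weights$weights[conds]),
                         stringsAsFactors = FALSE)
  comorbidity_points <- as.integer(sum(itemized$weight))
  age_points <- cci_age_points(case$age)
  score <- comorbidity_points + age_points
  structure(list(
    comorbidity_points = comorbidity_points,
    age_points = age_points,
    score = score,
    ten_year_survival = ten_year_survival(score),
    itemized = itemized
  ), class = "cci_result")
}

#' Estimated ten-year survival from a Charlson score
#'
#' The classical transform \eqn{0.983^{\exp(0.9 \cdot score)}}, clamped to
#' \eqn{[0, 1]}. A score of 0 gives 0.983; survival is strictly decreasing
#' in the score.
#'
#' @param score Non-negative integer Charlson score (comorbidity plus age
#'   points).
#' @return Probability in \eqn{[0, 1]}.
#' @export
ten_year_survival <- function(score) {
  if (!is.numeric(score) || any(is.na(score)) || any(score < 0)) {
    domain_error("Charlson score must be a non-negative number")
  }
  pmin(pmax(0.983 ^ exp(0.9 * score), 0), 1)
}

#' Gate configuration
#'
#' @param age_limit Maximum age permitted to proceed to screening
#'   recommendation (strictly greater ages are refused). Default 72.
#' @param survival_threshold Minimum estimated ten-year survival counted as
#'   "expected to live at least 10 years". Default 0.50.
#' @param enabled Set \code{FALSE} to bypass the gate entirely (clinician
#'   discretion); every case is then eligible.
#' @return A \code{gate_config} list.
#' @export
gate_config <- function(age_limit = 72L, survival_threshold = 0.5,
                        enabled = TRUE) {
  structure(list(age_limit = as.integer(age_limit),
                 survival_threshold = survival_threshold,
                 enabled = isTRUE(enabled)),
            class = "gate_config")
}

#' Apply the age and life-expectancy gates
#'
#' A case is refused when the patient is older than the configured age limit
#' or when the estimated ten-year survival falls below the configured
#' threshold; both reasons are reported when both fail (age gate evaluated
#' first). The gate is a pure function of (case, cci, config).
#'
#' @param case A \code{case_scenario}.
#' @param cci Its \code{cci_result}.
#' @param config A \code{\link{gate_config}}.
#' @return Object of class \code{gate_decision} with fields \code{eligible},
#'   \code{reasons}, \code{age_limit_used}, \code{survival_threshold_used}.
#' @export
screening_gate <- function(case, cci, config = gate_config()) {
  stopifnot(inherits(case, "case_scenario"), inherits(cci, "cci_result"))
  reasons <- character()
  if (config$enabled) {
    if (case$age > config$age_limit) reasons <- c(reasons, "age_over_limit")
    if (cci$ten_year_survival < config$survival_threshold) {
      reasons <- c(reasons, "life_expectancy_under_10y")
    }
  }
  structure(list(eligible = length(reasons) == 0L,
                 reasons = reasons,
                 age_limit_used = config$age_limit,
                 survival_threshold_used = config$survival_threshold),
            class = "gate_decision")
}

#' @export
print.cci_result <- function(x, ...) {
  cat(sprintf("CCI score %d (comorbidity %d + age %d); 10-year survival %.3f\n",
              x$score, x$comorbidity_points, x$age_points, x$ten_year_survival))
  invisible(x)
}

#' @export
print.gate_decision <- function(x, ...) {
  if (x$eligible) cat("gate: eligible\n")
  else cat("gate: refused (", paste(x$reasons, collapse = ", "), ")\n", sep = "")
  invisible(x)
}
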