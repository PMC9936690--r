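#' Build a scenario configuration from a plain named list
#'
#' Translates the flat key set used in configuration files into a
#' [scenario_config()]. Recognised keys: `target` (the scenario /
#' calibrated summary: `prevalence`, `relative_risk`, `risk_difference`,
#' `c_statistic`, `marginal_hazard_ratio`), `target_value`, `bracket`
#' (length-2), `tolerance`, `max_iterations`, `seed`, `n_continuous`,
#' `n_binary`, `binary_p`, `population_size`, `outcome_coefficients`,
#' `outcome_intercept`, `outcome_scale`, `treatment_coefficients`,
#' `treatment_intercept`, `baseline_family`, `baseline_rate`,
#' `baseline_shape`, `common_random_numbers`, `fitted_scores`.
#' Coefficient lists are given on the log scale. Unknown keys fail
#' validation so typos do not pass silently.
#'
#' @param config Named list, e.g. from `yaml::read_yaml()`.
#' @return A [scenario_config()].
#' @export
scenario_config_from_list <- function(config) {
  if (!is.list(config) || is.null(names(config))) {
    spec_error("config must be a named list")
  }
  known <- c("target", "scenario", "target_value", "bracket", "tolerance",
             "max_iterations", "seed", "n_continuous", "n_binary", "binary_p",
             "population_size", "outcome_coefficients", "outcome_intercept",
             "outcome_scale", "treatment_coefficients", "treatment_intercept",
             "baseline_family", "baseline_rate", "baseline_shape",
             "common_random_numbers", "fitted_scores")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    spec_error(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  }
  get_or <- function(key, default) if (!is.null(config[[key]])) config[[key]] else default

  scenario <- get_or("scenario", get_or("target", NULL))
  if (is.null(scenario)) spec_error("config must name the calibrated target ('target:' key)")

  cov_spec <- covariate_spec(
    n_continuous = get_or("n_continuous", 5L),
    n_binary = get_or("n_binary", 5L),
    binary_prob = get_or("binary_p", 0.5),
    population_size = get_or("population_size", 1e6))

  if (is.null(config$outcome_coefficients)) {
    spec_error("config must give outcome_coefficients (log scale)")
  }
  beta <- as.numeric(unlist(config$outcome_coefficients))

  outcome_model <- if (identical(scenario, "marginal_hazard_ratio")) {
    survival_spec(baseline_family = get_or("baseline_family", "exponential"),
                  rate = get_or("baseline_rate", 1),
                  shape = get_or("baseline_shape", 1),
                  coefficients = beta)
  } else {
    logistic_spec(intercept = get_or("outcome_intercept", 0),
                  coefficients = beta,
                  scale = get_or("outcome_scale", 1))
  }

  treatment_model <- NULL
  if (!is.null(config$treatment_coefficients)) {
    treatment_model <- logistic_spec(
      intercept = get_or("treatment_intercept", 0),
      coefficients = as.numeric(unlist(config$treatment_coefficients)))
  }

  if (is.null(config$target_value)) spec_error("config must give target_value")
  br <- get_or("bracket", c(-10, 10))
  if (identical(scenario, "joint")) {
    # joint runs need two targets (prevalence, c-statistic) and two brackets
    if (!is.list(br) || length(br) != 2L) {
      spec_error("joint config needs bracket: a list of two 2-number intervals")
    }
    br <- lapply(br, function(b) bracket(as.numeric(b[[1]]), as.numeric(b[[2]])))
  } else {
    if (length(br) != 2L) spec_error("bracket must be two numbers")
    br <- bracket(as.numeric(br[[1]]), as.numeric(br[[2]]))
  }

  scenario_config(
    scenario = scenario,
    covariate_spec = cov_spec,
    outcome_model = outcome_model,
    target_value = as.numeric(unlist(config$target_value)),
    bracket = br,
    settings = bisection_settings(
      max_iterations = get_or("max_iterations", 25L),
      tolerance = get_or("tolerance", 0.001),
      direction = "increasing"),
    treatment_model = treatment_model,
    seed = get_or("seed", 1L),
    common_random_numbers = isTRUE(config$common_random_numbers),
    fitted_scores = !isFALSE(config$fitted_scores))
}

#' Write a calibration result as structured text
#'
#' Emits the result fields (`final_parameter`, `final_summary`, `target`,
#' `converged`, `iterations`, `seed`) as `key: value` lines; the trace
#' itself goes through [write_trace()].
#'
#' @param result A `"dgp_calibration"`.
#' @param path File path.
#' @export
write_calibration_result <- function(result, path) {
  stopifnot(inherits(result, "dgp_calibration"))
  lines <- c(
    sprintf("final_parameter: %.17g", result$final_parameter),
    sprintf("final_summary: %.17g", result$final_summary),
    sprintf("target: %.17g", result$target),
    sprintf("converged: %s", tolower(as.character(result$converged))),
    sprintf("iterations: %d", nrow(result$trace)),
    sprintf("seed: %d", result$seed))
  writeLines(lines, path)
  invisible(path)
}
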