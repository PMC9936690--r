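#' Scenario configuration for a calibration run
#'
#' Bundles everything one calibration scenario needs: the covariate
#' specification, the outcome (and optionally treatment) model, the target
#' summary, the initial bracket and the bisection settings.
#'
#' Scenarios and the parameter each calibrates:
#' * `"prevalence"` — outcome-model intercept for a target outcome
#'   prevalence (also used, with the treatment model in the outcome slot,
#'   to calibrate treatment prevalence);
#' * `"relative_risk"` / `"risk_difference"` — treatment log-odds ratio for
#'   a target marginal relative risk / risk difference on potential
#'   outcomes;
#' * `"c_statistic"` — global coefficient scale for a target c-statistic of
#'   the model fitted to the simulated sample;
#' * `"marginal_hazard_ratio"` — conditional treatment log-hazard ratio for
#'   a target marginal hazard ratio from the concatenated-arms Cox fit;
#' * `"joint"` — outcome intercept and coefficient scale calibrated
#'   sequentially for simultaneous prevalence and c-statistic targets.
#'
#' @param scenario One of the scenario names above.
#' @param covariate_spec A [covariate_spec()].
#' @param outcome_model A [logistic_spec()] (binary scenarios) or
#'   [survival_spec()] (`"marginal_hazard_ratio"`).
#' @param target_value Target summary: in (0, 1) for prevalence and
#'   c-statistic, positive for relative risk and hazard ratio, in (-1, 1)
#'   for risk difference. For `"joint"`, a length-2 vector
#'   `c(prevalence, c_statistic)`.
#' @param bracket Initial [bracket()] for the calibrated parameter; for
#'   `"joint"`, a list of two brackets (intercept, scale).
#' @param settings A [bisection_settings()]; for `"joint"`, a list of two.
#' @param treatment_model Optional [logistic_spec()] describing treatment
#'   selection; part of the data-generating process a study would go on to
#'   use, but not consumed by the potential-outcome evaluators themselves.
#' @param seed Integer seed: drives the super-population draw and all
#'   evaluation substreams.
#' @param common_random_numbers If `TRUE`, every bisection evaluation
#'   reuses one fixed seed, making the empirical evaluator a deterministic
#'   monotone function of the parameter (no decision-flip risk near
#'   convergence). Default `FALSE`: independent substream per evaluation.
#' @param fitted_scores (`"c_statistic"` only) score with the fitted
#'   model's linear predictor (`TRUE`, default) or with the true linear
#'   predictor (`FALSE`, a fast mode that skips the logistic fit and is
#'   asymptotically equivalent at large `N`).
#' @param outer_max (`"joint"` only) maximum sweeps for
#'   [sequential_calibrate()].
#' @return An object of class `"dgp_scenario_config"`.
#' @export
scenario_config <- function(scenario = c("prevalence", "relative_risk",
                                         "risk_difference", "c_statistic",
                                         "marginal_hazard_ratio", "joint"),
                            covariate_spec, outcome_model, target_value,
                            bracket, settings = bisection_settings(),
                            treatment_model = NULL, seed = 1L,
                            common_random_numbers = FALSE,
                            fitted_scores = TRUE, outer_max = 5L) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(covariate_spec, "dgp_covariate_spec"))
  p <- covariate_spec$n_continuous + covariate_spec$n_binary

  check_target <- function(value, kind) {
    if (!is_scalar_number(value)) spec_error("target_value must be finite")
    ok <- switch(kind,
                 unit_open = value > 0 && value < 1,
                 positive = value > 0,
                 signed_unit = value > -1 && value < 1)
    if (!ok) {
      spec_error(sprintf(
        "target_value %g is outside the natural range of a %s target", value,
        switch(kind, unit_open = "(0,1)", positive = "positive-ratio",
               signed_unit = "(-1,1)")))
    }
  }

  if (scenario == "joint") {
    if (length(target_value) != 2L) {
      spec_error("joint scenario needs target_value = c(prevalence, c_statistic)")
    }
    check_target(target_value[1], "unit_open")
    check_target(target_value[2], "unit_open")
    if (!is.list(bracket) || length(bracket) != 2L) {
      spec_error("joint scenario needs a list of two brackets (intercept, scale)")
    }
    bracket <- lapply(bracket, as_bracket)
    if (inherits(settings, "dgp_bisection_settings")) settings <- list(settings, settings)
  } else {
    kind <- switch(scenario,
                   prevalence = "unit_open", c_statistic = "unit_open",
                   relative_risk = "positive", marginal_hazard_ratio = "positive",
                   risk_difference = "signed_unit")
    check_target(target_value, kind)
    bracket <- as_bracket(bracket)
    stopifnot(inherits(settings, "dgp_bisection_settings"))
  }

  if (scenario == "marginal_hazard_ratio") {
    stopifnot(inherits(outcome_model, "dgp_survival_spec"))
  } else {
    stopifnot(inherits(outcome_model, "dgp_logistic_spec"))
  }
  if (length(outcome_model$coefficients) != p) {
    spec_error("outcome model coefficient count does not match the covariate spec")
  }
  if (!is.null(treatment_model)) {
    stopifnot(inherits(treatment_model, "dgp_logistic_spec"))
    if (length(treatment_model$coefficients) != p) {
      spec_error("treatment model coefficient count does not match the covariate spec")
    }
  }

  structure(
    list(scenario = scenario, covariate_spec = covariate_spec,
         outcome_model = outcome_model, treatment_model = treatment_model,
         target_value = target_value, bracket = bracket, settings = settings,
         seed = as.integer(seed),
         common_random_numbers = isTRUE(common_random_numbers),
         fitted_scores = isTRUE(fitted_scores),
         outer_max = as.integer(outer_max)),
    class = "dgp_scenario_config"
  )
}

# Build the scenario's parameter -> summary evaluator over a frozen
# super-population. Returned functions have signature (param, seed).
scenario_evaluator <- function(config, population) {
  om <- config$outcome_model
  switch(config$scenario,
    prevalence = function(b0, seed) {
      spec <- om
      spec$intercept <- b0
      empirical_prevalence(
        simulate_binary_outcomes(linear_predictor(population, spec), seed = seed))
    },
    relative_risk = function(gamma, seed) {
      spec <- om
      spec$treatment_log_or <- gamma
      po <- potential_binary_outcomes(population, spec, seed = seed,
                                      shared_uniforms = config$common_random_numbers)
      marginal_relative_risk(po$y0, po$y1)
    },
    risk_difference = function(gamma, seed) {
      spec <- om
      spec$treatment_log_or <- gamma
      po <- potential_binary_outcomes(population, spec, seed = seed,
                                      shared_uniforms = config$common_random_numbers)
      marginal_risk_difference(po$y0, po$y1)
    },
    c_statistic = function(sigma, seed) {
      spec <- om
      spec$scale <- sigma
      y <- simulate_binary_outcomes(linear_predictor(population, spec), seed = seed)
      scores <- if (config$fitted_scores) {
        fit_logistic_mle(population, y)$linear_predictors
      } else {
        linear_predictor(population, spec)
      }
      c_statistic(scores, y)
    },
    marginal_hazard_ratio = function(gamma, seed) {
      spec <- om
      spec$treatment_log_hr <- gamma
      pt <- potential_event_times(population, spec, seed = seed,
                                  shared_uniforms = config$common_random_numbers)
      marginal_hazard_ratio(pt$t0, pt$t1)
    },
    spec_error(sprintf("no single-parameter evaluator for scenario '%s'", config$scenario))
  )
}

#' Run a calibration scenario end-to-end
#'
#' Builds the super-population once from the config seed, constructs the
#' scenario's summary evaluator over it, runs [bisect_calibrate()] (or
#' [sequential_calibrate()] for the `"joint"` scenario), and optionally
#' writes the iteration trace as delimited text.
#'
#' When `common_random_numbers = FALSE` (default), evaluation `k` of the
#' bisection uses substream seed `seed + 1 + k`; with common random
#' numbers every evaluation reuses the same outcome seed.
#'
#' @param config A [scenario_config()].
#' @param trace_file Optional path for the trace table
#'   (`iteration,lower,upper,midpoint,summary,target,decision`).
#' @param check_endpoints Verify that the bracket endpoints straddle the
#'   target (two extra full-size evaluations). Default `TRUE`.
#' @return A `"dgp_calibration"` (or `"dgp_sequential_calibration"` for
#'   `"joint"`) result.
#' @export
run_scenario <- function(config, trace_file = NULL, check_endpoints = TRUE) {
  stopifnot(inherits(config, "dgp_scenario_config"))
  population <- generate_superpopulation(config$covariate_spec, seed = config$seed)
  outcome_seed_base <- substream_seed(config$seed, 7919L)

  if (config$scenario == "joint") {
    result <- run_joint_scenario(config, population, outcome_seed_base)
  } else {
    evaluator <- scenario_evaluator(config, population)
    wrapped <- if (config$common_random_numbers) {
      fixed <- outcome_seed_base
      function(x, seed) evaluator(x, fixed)
    } else {
      evaluator
    }
    result <- bisect_calibrate(wrapped, config$target_value, config$bracket,
                               config$settings, seed = outcome_seed_base,
                               check_endpoints = check_endpoints)
  }
  if (!is.null(trace_file)) {
    if (config$scenario == "joint") {
      for (nm in names(result$results)) {
        write_trace(result$results[[nm]],
                    file.path(dirname(trace_file),
                              paste0(nm, "-", basename(trace_file))))
      }
    } else {
      write_trace(result, trace_file)
    }
  }
  result
}

# Joint prevalence + c-statistic calibration: intercept and coefficient
# scale interact (the scale shifts prevalence), so sweeps must repeat.
run_joint_scenario <- function(config, population, outcome_seed_base) {
  om <- config$outcome_model
  eval_at <- function(params, seed, what) {
    spec <- om
    spec$intercept <- params$intercept
    spec$scale <- params$scale
    y <- simulate_binary_outcomes(linear_predictor(population, spec), seed = seed)
    if (what == "prevalence") return(empirical_prevalence(y))
    scores <- if (config$fitted_scores) {
      fit_logistic_mle(population, y)$linear_predictors
    } else {
      linear_predictor(population, spec)
    }
    c_statistic(scores, y)
  }
  problems <- list(
    calibration_problem(
      "intercept",
      function(params, seed) eval_at(params, seed, "prevalence"),
      target = config$target_value[1], bracket = config$bracket[[1]],
      settings = config$settings[[1]]),
    calibration_problem(
      "scale",
      function(params, seed) eval_at(params, seed, "c_statistic"),
      target = config$target_value[2], bracket = config$bracket[[2]],
      settings = config$settings[[2]])
  )
  # start the sweep at the outcome model's own values (e.g. scale 1), not
  # at the bracket midpoints: the first intercept pass should see the
  # unscaled model
  sequential_calibrate(problems, outer_max = config$outer_max,
                       seed = outcome_seed_base,
                       initial = list(intercept = om$intercept, scale = om$scale))
}
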