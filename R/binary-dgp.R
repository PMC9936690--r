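#' Logistic outcome / treatment model specification
#'
#' Parameterises the logistic models used to simulate binary outcomes and
#' treatment assignment. The linear predictor for subject `i` is
#' `intercept + treatment_log_or * Z_i + scale * sum_j coefficients_j * X_ij`:
#' the global `scale` multiplies the covariate sum only (never the intercept
#' or the treatment term), so it rescales every covariate log-odds ratio
#' while preserving all their ratios — the knob used to calibrate the model
#' c-statistic.
#'
#' @param intercept Intercept on the log-odds scale.
#' @param coefficients Covariate coefficients (log-odds ratios), one per
#'   super-population column.
#' @param treatment_log_or Log-odds ratio for a binary treatment (default 0,
#'   i.e. no treatment term).
#' @param scale Nonnegative global multiplier of the covariate sum
#'   (default 1).
#' @return An object of class `"dgp_logistic_spec"`.
#' @export
logistic_spec <- function(intercept, coefficients, treatment_log_or = 0, scale = 1) {
  if (!is_scalar_number(intercept)) spec_error("intercept must be a finite scalar")
  if (!is.numeric(coefficients) || length(coefficients) < 1 || anyNA(coefficients)) {
    spec_error("coefficients must be a nonempty numeric vector")
  }
  if (!is_scalar_number(treatment_log_or)) spec_error("treatment_log_or must be a finite scalar")
  if (!is_scalar_number(scale) || scale < 0) spec_error("scale must be nonnegative")
  structure(
    list(intercept = intercept, coefficients = as.numeric(coefficients),
         treatment_log_or = treatment_log_or, scale = scale),
    class = "dgp_logistic_spec"
  )
}

#' Linear predictor of a logistic model over the super-population
#'
#' @param population A [generate_superpopulation()] result.
#' @param spec A [logistic_spec()].
#' @param treatment Optional 0/1 treatment vector `Z`; when supplied, the
#'   term `treatment_log_or * Z_i` is added. Pass a scalar `0` or `1` to set
#'   all subjects to one arm (the potential-outcomes device).
#' @return Length-`N` numeric vector
#'   `intercept + treatment_log_or * Z + scale * X %*% coefficients`.
#' @export
linear_predictor <- function(population, spec, treatment = NULL) {
  stopifnot(inherits(population, "dgp_superpopulation"),
            inherits(spec, "dgp_logistic_spec"))
  x <- population$values
  if (length(spec$coefficients) != ncol(x)) {
    spec_error(sprintf("model has %d coefficients but the super-population has %d covariates",
                       length(spec$coefficients), ncol(x)))
  }
  lp <- spec$intercept + spec$scale * drop(x %*% spec$coefficients)
  if (!is.null(treatment)) {
    z <- if (length(treatment) == 1L) rep(treatment, nrow(x)) else as.numeric(treatment)
    if (length(z) != nrow(x)) spec_error("treatment vector length does not match the population")
    lp <- lp + spec$treatment_log_or * z
  }
  lp
}

#' Simulate Bernoulli outcomes from a linear predictor
#'
#' Draws `Y_i ~ Bernoulli(expit(lp_i))` independently across subjects.
#'
#' @param lp Length-`N` finite linear predictor (log-odds scale).
#' @param seed Integer seed for the draw.
#' @return Integer 0/1 vector of length `N`.
#' @export
simulate_binary_outcomes <- function(lp, seed = 1L) {
  if (!is.numeric(lp) || length(lp) == 0L || !all(is.finite(lp))) {
    eval_error("linear predictor must be a nonempty finite numeric vector")
  }
  withr::with_seed(as.integer(seed), {
    as.integer(stats::runif(length(lp)) < inv_logit(lp))
  })
}

#' Empirical prevalence of a binary vector
#'
#' The arithmetic mean of 0/1 outcomes: the summary compared against the
#' target prevalence during intercept calibration.
#'
#' @param outcomes 0/1 vector.
#' @return Proportion in `[0, 1]`.
#' @export
empirical_prevalence <- function(outcomes) {
  if (length(outcomes) == 0L) spec_error("outcomes vector is empty")
  mean(outcomes)
}

#' Simulate treatment assignment from a logistic treatment-selection model
#'
#' @param population A super-population.
#' @param treatment_model A [logistic_spec()] with `treatment_log_or = 0`
#'   (a treatment model cannot itself contain a treatment term). Treatment
#'   prevalence is governed by its intercept.
#' @param seed Integer seed.
#' @return Integer 0/1 assignment vector `Z`.
#' @export
simulate_treatment <- function(population, treatment_model, seed = 1L) {
  stopifnot(inherits(treatment_model, "dgp_logistic_spec"))
  if (treatment_model$treatment_log_or != 0) {
    spec_error("a treatment-selection model must have treatment_log_or = 0")
  }
  simulate_binary_outcomes(linear_predictor(population, treatment_model), seed = seed)
}

#' Potential binary outcomes under control and treatment
#'
#' Simulates each subject's two potential outcomes by setting the treatment
#' indicator to 0 for everyone (giving `Y(0)`) and then to 1 for everyone
#' (giving `Y(1)`), both from the same super-population and model. By
#' default the two arms use independent Bernoulli draws; with
#' `shared_uniforms = TRUE` a single uniform panel is compared against both
#' arms' probabilities (common random numbers), which couples the arms and
#' makes `Y(1) >= Y(0)` whenever `treatment_log_or >= 0`.
#'
#' @inheritParams simulate_treatment
#' @param spec Outcome [logistic_spec()] including its `treatment_log_or`.
#' @param shared_uniforms Couple the two arms on one uniform panel.
#' @return List with integer 0/1 vectors `y0` and `y1`.
#' @export
potential_binary_outcomes <- function(population, spec, seed = 1L,
                                      shared_uniforms = FALSE) {
  lp0 <- linear_predictor(population, spec, treatment = 0)
  lp1 <- lp0 + spec$treatment_log_or
  if (shared_uniforms) {
    u <- withr::with_seed(as.integer(seed), stats::runif(length(lp0)))
    list(y0 = as.integer(u < inv_logit(lp0)), y1 = as.integer(u < inv_logit(lp1)))
  } else {
    list(y0 = simulate_binary_outcomes(lp0, seed = substream_seed(seed, 0L)),
         y1 = simulate_binary_outcomes(lp1, seed = substream_seed(seed, 1L)))
  }
}

#' Marginal (population-average) relative risk
#'
#' `E[Y(1)] / E[Y(0)]` over the super-population of potential outcomes.
#'
#' @param y0,y1 0/1 potential-outcome vectors under control and treatment.
#' @return Positive scalar.
#' @export
marginal_relative_risk <- function(y0, y1) {
  p0 <- empirical_prevalence(y0)
  if (p0 == 0) {
    eval_error("control-arm prevalence is zero: relative risk is undefined")
  }
  empirical_prevalence(y1) / p0
}

#' Marginal risk difference (average treatment effect)
#'
#' `E[Y(1)] - E[Y(0)]` over the super-population of potential outcomes.
#'
#' @inheritParams marginal_relative_risk
#' @return Scalar in `[-1, 1]`.
#' @export
marginal_risk_difference <- function(y0, y1) {
  if (length(y0) != length(y1)) spec_error("potential-outcome vectors differ in length")
  empirical_prevalence(y1) - empirical_prevalence(y0)
}
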