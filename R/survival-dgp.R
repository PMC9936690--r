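#' Proportional-hazards model specification for event-time simulation
#'
#' Parameterises the hazard model
#' `log h_i(t) = log h_0(t) + treatment_log_hr * Z_i + sum_j coefficients_j * X_ij`
#' with an exponential (`shape = 1`) or Weibull baseline
#' `h_0(t) = rate * shape * t^(shape - 1)`. The treatment coefficient is the
#' *conditional* log-hazard ratio; the marginal hazard ratio it induces is
#' attenuated toward the null whenever the covariate effects are nonzero
#' (non-collapsibility), which is exactly why it must be calibrated.
#'
#' With no censoring, the marginal hazard-ratio evaluator depends on the
#' event times only through their ordering, so it is invariant to `rate`
#' and `shape`; the exponential baseline with `rate = 1` is therefore a
#' harmless default.
#'
#' @param baseline_family `"exponential"` or `"weibull"`.
#' @param rate Positive baseline hazard scale.
#' @param shape Positive Weibull shape (forced to 1 for exponential).
#' @param coefficients Covariate log-hazard ratios, one per column.
#' @param treatment_log_hr Conditional log-hazard ratio for treatment.
#' @return An object of class `"dgp_survival_spec"`.
#' @export
survival_spec <- function(baseline_family = c("exponential", "weibull"),
                          rate = 1, shape = 1, coefficients,
                          treatment_log_hr = 0) {
  baseline_family <- match.arg(baseline_family)
  if (!is_scalar_number(rate) || rate <= 0) spec_error("rate must be positive")
  if (!is_scalar_number(shape) || shape <= 0) spec_error("shape must be positive")
  if (baseline_family == "exponential") shape <- 1
  if (!is.numeric(coefficients) || length(coefficients) < 1 || anyNA(coefficients)) {
    spec_error("coefficients must be a nonempty numeric vector")
  }
  if (!is_scalar_number(treatment_log_hr)) spec_error("treatment_log_hr must be a finite scalar")
  structure(
    list(baseline_family = baseline_family, rate = rate, shape = shape,
         coefficients = as.numeric(coefficients),
         treatment_log_hr = treatment_log_hr),
    class = "dgp_survival_spec"
  )
}

#' Simulate event times by inverting the cumulative hazard
#'
#' Bender-style inverse-CDF sampling for proportional-hazards models:
#' `T = (-log(U) / (rate * exp(LP)))^(1/shape)` with
#' `LP = treatment_log_hr * Z + X %*% coefficients`, so larger linear
#' predictors give stochastically shorter times. No censoring is applied;
#' every record is an event.
#'
#' @param population A super-population.
#' @param treatment 0/1 vector `Z`, or a scalar 0/1 applied to everyone.
#' @param spec A [survival_spec()].
#' @param uniforms Length-`N` vector strictly inside (0, 1).
#' @return List with `times` (positive event times) and `event`
#'   (all ones).
#' @export
bender_event_times <- function(population, treatment, spec, uniforms) {
  stopifnot(inherits(population, "dgp_superpopulation"),
            inherits(spec, "dgp_survival_spec"))
  x <- population$values
  if (length(spec$coefficients) != ncol(x)) {
    spec_error("coefficient length does not match the super-population")
  }
  n <- nrow(x)
  z <- if (length(treatment) == 1L) rep(treatment, n) else as.numeric(treatment)
  if (length(z) != n) spec_error("treatment vector length does not match the population")
  if (length(uniforms) != n) spec_error("uniform vector length does not match the population")
  if (any(uniforms <= 0) || any(uniforms >= 1)) {
    eval_error("uniforms must lie strictly inside (0, 1)")
  }
  lp <- spec$treatment_log_hr * z + drop(x %*% spec$coefficients)
  times <- (-log(uniforms) / (spec$rate * exp(lp)))^(1 / spec$shape)
  list(times = times, event = rep(1L, n))
}

#' Potential event times under control and treatment
#'
#' Generates each subject's event time with the treatment indicator set to 0
#' for everyone and then to 1 for everyone, from the same super-population
#' and hazard model. Independent uniform panels per arm by default; with
#' `shared_uniforms = TRUE` both arms reuse one panel, which for the
#' exponential baseline makes `T(1) = T(0) * exp(-treatment_log_hr)`
#' elementwise.
#'
#' @inheritParams bender_event_times
#' @param seed Integer seed for the uniform panels.
#' @param shared_uniforms Reuse one uniform panel for both arms.
#' @return List with event-time lists `t0` and `t1`.
#' @export
potential_event_times <- function(population, spec, seed = 1L,
                                  shared_uniforms = FALSE) {
  n <- nrow(population$values)
  draw <- function(s) withr::with_seed(s, stats::runif(n))
  if (shared_uniforms) {
    u0 <- u1 <- draw(as.integer(seed))
  } else {
    u0 <- draw(substream_seed(seed, 0L))
    u1 <- draw(substream_seed(seed, 1L))
  }
  list(t0 = bender_event_times(population, 0, spec, u0),
       t1 = bender_event_times(population, 1, spec, u1))
}

# Collapse a survival sample into per-unique-time sufficient statistics for
# the Breslow partial likelihood of a single binary covariate:
# events (d, d1) and risk-set sizes (n_at_risk, n1_at_risk) at each time.
cox_sufficient_stats <- function(times, group, event) {
  ord <- order(times)
  t_s <- times[ord]
  z_s <- group[ord]
  e_s <- event[ord]
  n <- length(t_s)
  n1_suffix <- rev(cumsum(rev(z_s)))
  if (!anyDuplicated(t_s)) {
    # continuous simulated times: every time is its own risk-set row
    d <- e_s
    d1 <- e_s * z_s
    at_risk <- n:1
    at_risk1 <- n1_suffix
  } else {
    first <- !duplicated(t_s)
    at_risk <- (n:1)[first]
    at_risk1 <- n1_suffix[first]
    grp <- cumsum(first)
    d <- as.vector(rowsum(e_s, grp))
    d1 <- as.vector(rowsum(e_s * z_s, grp))
  }
  keep <- d > 0
  list(d = d[keep], d1 = d1[keep],
       n_risk = at_risk[keep], n1_risk = at_risk1[keep])
}

cox_partial_loglik <- function(b, ss) {
  n0 <- ss$n_risk - ss$n1_risk
  sum(ss$d1) * b - sum(ss$d * log(n0 + ss$n1_risk * exp(b)))
}

#' Univariate Cox fit for a binary group by Newton iteration
#'
#' Maximizes the Cox partial likelihood for a single binary covariate by
#' safeguarded Newton-Raphson (step-halving on the partial log-likelihood),
#' using the Breslow convention for tied event times. Convergence is
#' declared when the absolute score falls below `convergence_tolerance`.
#'
#' @param times Positive event/censoring times.
#' @param group 0/1 group indicator; both groups must be present.
#' @param event 0/1 event indicators (default: all events, the only case
#'   the calibration recipes produce; censoring is supported so the fitter
#'   is reusable).
#' @param convergence_tolerance Absolute bound on the score at convergence.
#' @param max_newton_steps Iteration budget.
#' @return An object of class `"dgp_cox_fit"`: `log_hazard_ratio`,
#'   `score`, `information`, `iterations`, `converged`.
#' @export
fit_cox_univariate <- function(times, group, event = NULL,
                               convergence_tolerance = 1e-9,
                               max_newton_steps = 50L) {
  times <- as.numeric(times)
  group <- as.numeric(group)
  if (length(times) != length(group)) spec_error("times and group differ in length")
  if (!all(group %in% c(0, 1))) spec_error("group must be 0/1")
  if (all(group == 0) || all(group == 1)) {
    spec_error("both groups must be present to estimate a hazard ratio")
  }
  if (is.null(event)) event <- rep(1L, length(times))
  if (length(unique(times[event == 1])) < 2L) {
    spec_error("at least two distinct event times are required")
  }
  ss <- cox_sufficient_stats(times, group, event)
  b <- 0
  ll <- cox_partial_loglik(b, ss)
  n0 <- ss$n_risk - ss$n1_risk
  converged <- FALSE
  iter <- 0L
  score <- information <- NA_real_
  # the score is a sum over events, so its attainable precision scales with
  # the event count; widen the absolute tolerance accordingly
  tol_eff <- max(convergence_tolerance, 1e-11 * sum(ss$d))
  while (iter < max_newton_steps) {
    iter <- iter + 1L
    eb <- exp(b)
    denom <- n0 + ss$n1_risk * eb
    frac <- ss$n1_risk * eb / denom
    score <- sum(ss$d1) - sum(ss$d * frac)
    information <- sum(ss$d * frac * (1 - frac))
    if (abs(score) <= tol_eff) {
      converged <- TRUE
      break
    }
    if (information <= 0) break
    delta <- score / information
    if (abs(delta) <= 1e-12 * max(1, abs(b))) {
      converged <- TRUE
      break
    }
    step <- 1
    repeat {
      cand <- b + step * delta
      ll_new <- cox_partial_loglik(cand, ss)
      if (is.finite(ll_new) && ll_new >= ll - 1e-9 * max(1, abs(ll))) break
      step <- step / 2
      if (step < 1e-8) break
    }
    if (step < 1e-8) break
    b <- cand
    ll <- ll_new
    if (abs(b) > 20) {
      fit_error(paste("monotone partial likelihood: one group's events all precede",
                      "the other's, so the hazard ratio diverges"))
    }
  }
  if (!converged) {
    fit_error("Cox partial-likelihood Newton iteration did not converge")
  }
  structure(
    list(log_hazard_ratio = b, score = score, information = information,
         iterations = iter, converged = converged),
    class = "dgp_cox_fit"
  )
}

#' @export
print.dgp_cox_fit <- function(x, ...) {
  cat(sprintf("Univariate Cox fit: log HR = %.7g (HR = %.7g), %d Newton steps\n",
              x$log_hazard_ratio, exp(x$log_hazard_ratio), x$iterations))
  invisible(x)
}

#' Marginal hazard ratio from concatenated potential outcomes
#'
#' Stacks the control-arm and treated-arm potential event times into one
#' dataset of `2N` records with an arm indicator, fits a univariate Cox
#' model on the arm indicator, and exponentiates the coefficient. Because
#' all records are events, the estimate depends only on the ordering of the
#' pooled times.
#'
#' @param t0,t1 Event-time lists from [potential_event_times()] (or any
#'   lists with a `times` element) for the control and treated arms.
#' @param convergence_tolerance Passed to [fit_cox_univariate()].
#' @return Positive scalar: the estimated marginal hazard ratio.
#' @export
marginal_hazard_ratio <- function(t0, t1, convergence_tolerance = 1e-9) {
  x0 <- if (is.list(t0)) t0$times else t0
  x1 <- if (is.list(t1)) t1$times else t1
  if (length(x0) != length(x1)) spec_error("potential-outcome arms differ in length")
  fit <- fit_cox_univariate(c(x0, x1), rep(c(0, 1), c(length(x0), length(x1))),
                            convergence_tolerance = convergence_tolerance)
  exp(fit$log_hazard_ratio)
}

#' Export concatenated potential-outcome survival data as delimited text
#'
#' Writes `time,event,arm` rows for the stacked control/treated records.
#'
#' @inheritParams marginal_hazard_ratio
#' @param path File path.
#' @export
write_potential_times <- function(t0, t1, path) {
  x0 <- if (is.list(t0)) t0$times else t0
  x1 <- if (is.list(t1)) t1$times else t1
  df <- data.frame(time = c(x0, x1), event = 1L,
                   arm = rep(c(0L, 1L), c(length(x0), length(x1))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
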