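#' Maximum-likelihood logistic regression by IRLS
#'
#' Fits the logistic model of the simulated sample (intercept plus one slope
#' per super-population column) by iteratively reweighted least squares,
#' with step-halving on the log-likelihood. Convergence is declared when the
#' largest absolute score (gradient) component falls below
#' `convergence_tolerance`. Used by the c-statistic calibration recipe,
#' which scores subjects with the fitted linear predictor.
#'
#' @param population A super-population.
#' @param outcomes 0/1 outcome vector of matching length.
#' @param convergence_tolerance Absolute bound on the score at convergence.
#' @param max_newton_steps Iteration budget.
#' @return An object of class `"dgp_logistic_fit"`: `coefficients`
#'   (named, `(Intercept)` first), `linear_predictors`, `converged`,
#'   `iterations`.
#' @export
fit_logistic_mle <- function(population, outcomes,
                             convergence_tolerance = 1e-6,
                             max_newton_steps = 50L) {
  stopifnot(inherits(population, "dgp_superpopulation"))
  y <- as.numeric(outcomes)
  x <- population$values
  if (length(y) != nrow(x)) spec_error("outcome length does not match the population")
  if (!all(y %in% c(0, 1))) spec_error("outcomes must be 0/1")
  if (all(y == 0) || all(y == 1)) {
    fit_error("both outcome classes must be present to fit a logistic model")
  }
  xm <- cbind("(Intercept)" = 1, x)
  p <- ncol(xm)
  beta <- numeric(p)
  # start the intercept at the empirical logit; covariates at zero
  beta[1] <- stats::qlogis(mean(y))
  loglik <- function(b) {
    lp <- drop(xm %*% b)
    # log(1 + e^lp) computed overflow-safely as max(lp, 0) + log1p(e^-|lp|)
    sum(y * lp - (pmax(lp, 0) + log1p(exp(-abs(lp)))))
  }
  ll <- loglik(beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_newton_steps) {
    iter <- iter + 1L
    lp <- drop(xm %*% beta)
    mu <- inv_logit(lp)
    score <- drop(crossprod(xm, y - mu))
    if (max(abs(score)) <= convergence_tolerance) {
      converged <- TRUE
      break
    }
    w <- mu * (1 - mu)
    info <- crossprod(xm, xm * w)
    delta <- tryCatch(solve(info, score),
                      error = function(e) fit_error(
                        "singular information matrix (possible separation or collinearity)"))
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- loglik(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      step <- step / 2
      if (step < 1e-8) fit_error("IRLS step-halving failed to improve the likelihood")
    }
    beta <- cand
    ll <- ll_new
    if (max(abs(beta)) > 30) {
      fit_error("diverging coefficients: the data are (quasi-)separated")
    }
  }
  if (!converged) {
    # accept a numerically flat score relative to the information scale
    lp <- drop(xm %*% beta)
    score <- drop(crossprod(xm, y - inv_logit(lp)))
    if (max(abs(score)) > sqrt(convergence_tolerance)) {
      fit_error("logistic MLE did not converge within the iteration budget")
    }
    converged <- TRUE
  }
  names(beta) <- colnames(xm)
  structure(
    list(coefficients = beta,
         linear_predictors = drop(xm %*% beta),
         converged = converged,
         iterations = iter),
    class = "dgp_logistic_fit"
  )
}

#' @export
print.dgp_logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic MLE (%d IRLS iterations)\n", x$iterations))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Concordance statistic (c-statistic / AUC)
#'
#' The probability that a uniformly random case receives a higher score
#' than a uniformly random control, with ties counted one-half — the area
#' under the ROC curve. Computed from rank sums in `O(N log N)`, so it is
#' invariant to any strictly increasing transform of the scores.
#'
#' @param scores Numeric risk scores (e.g. a fitted linear predictor).
#' @param outcomes 0/1 vector of the same length; both classes must be
#'   present.
#' @return Scalar in `[0, 1]`.
#' @export
c_statistic <- function(scores, outcomes) {
  if (length(scores) != length(outcomes)) spec_error("scores and outcomes differ in length")
  y <- as.numeric(outcomes)
  n1 <- as.double(sum(y == 1))
  n0 <- as.double(sum(y == 0))
  if (n1 == 0 || n0 == 0) {
    fit_error("c-statistic is undefined when one outcome class is absent")
  }
  r <- rank(scores)  # midranks handle ties as one-half
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
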