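#' Bracketing interval for a calibration parameter
#'
#' A bracket is the initial search interval for the parameter being
#' calibrated, e.g. `(-10, 10)` for a logistic intercept. The two endpoint
#' summaries must straddle the target value (checked by
#' [bisect_calibrate()] unless endpoint verification is disabled).
#'
#' @param lower,upper Finite numbers with `lower < upper`, in the units of
#'   the parameter being calibrated.
#' @return An object of class `"dgp_bracket"`.
#' @examples
#' bracket(-10, 10)
#' @export
bracket <- function(lower, upper) {
  if (!is_scalar_number(lower) || !is_scalar_number(upper)) {
    spec_error("bracket endpoints must be finite scalars")
  }
  if (lower >= upper) {
    spec_error(sprintf("bracket lower (%g) must be below upper (%g)", lower, upper))
  }
  structure(list(lower = lower, upper = upper), class = "dgp_bracket")
}

as_bracket <- function(x) {
  if (inherits(x, "dgp_bracket")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(bracket(x[1L], x[2L]))
  spec_error("expected a bracket() or a numeric vector of length 2")
}

#' Settings for the bisection engine
#'
#' @param max_iterations Maximum number of interval halvings (the iteration
#'   budget `K`). After `K` iterations the bracket width is `1/2^K` of the
#'   initial width.
#' @param tolerance Nonnegative stopping tolerance in the units of the
#'   summary: iteration stops at the first midpoint whose summary is within
#'   `tolerance` of the target. `0` forces the full iteration budget.
#' @param direction `"increasing"` if the evaluator's expected summary is
#'   increasing in the parameter (e.g. prevalence in the intercept),
#'   `"decreasing"` otherwise. Decreasing evaluators are handled by
#'   negating the comparison, so traces stay in natural units.
#' @return An object of class `"dgp_bisection_settings"`.
#' @export
bisection_settings <- function(max_iterations = 25L,
                               tolerance = 0.001,
                               direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  if (!is_scalar_number(max_iterations) || max_iterations < 1) {
    spec_error("max_iterations must be a positive integer")
  }
  if (!is_scalar_number(tolerance) || tolerance < 0) {
    spec_error("tolerance must be a nonnegative number")
  }
  structure(
    list(max_iterations = as.integer(max_iterations),
         tolerance = tolerance,
         direction = direction),
    class = "dgp_bisection_settings"
  )
}

# Evaluators may be written as f(parameter) or f(parameter, seed); the
# engine passes a substream seed when the signature accepts one.
call_evaluator <- function(evaluator, parameter, seed) {
  fm <- formals(args(evaluator))
  value <- if (length(fm) >= 2L || "..." %in% names(fm)) {
    evaluator(parameter, seed)
  } else {
    evaluator(parameter)
  }
  if (!is_scalar_number(value)) {
    eval_error(sprintf("evaluator returned a non-finite summary at parameter %g", parameter),
               parameter = parameter)
  }
  value
}

#' Calibrate a parameter by iterative bisection of a stochastic evaluator
#'
#' Repeatedly halves a bracketing interval to find the parameter value at
#' which a (possibly stochastic, monotone-in-expectation) evaluator attains
#' a target summary value. At each iteration the evaluator is run at the
#' bracket midpoint; if the summary falls short of the target the upper
#' half of the interval is kept, otherwise the lower half (comparisons are
#' reversed for `direction = "decreasing"`). Iteration stops at the first
#' summary within `tolerance` of the target, or after `max_iterations`.
#'
#' Each evaluation receives an independent, deterministically derived
#' substream seed (`seed + iteration`), so runs are reproducible while
#' Monte Carlo evaluations stay independent. Evaluators that ignore the
#' seed (or close over a fixed one, the common-random-numbers mode) are
#' also supported.
#'
#' @param evaluator A function `f(parameter)` or `f(parameter, seed)`
#'   returning a scalar summary (a prevalence, relative risk, c-statistic,
#'   hazard ratio, ...), monotone in the parameter in expectation.
#' @param target The target summary value.
#' @param bracket Initial interval, a [bracket()] or numeric length-2 vector.
#'   Its endpoint summaries must straddle `target`.
#' @param settings A [bisection_settings()] object.
#' @param seed Integer base seed for the evaluation substreams.
#' @param check_endpoints If `TRUE` (default), evaluate both endpoints
#'   first and fail with a bracket error if their summaries do not straddle
#'   the target. Set `FALSE` to accept the bracket on trust and save two
#'   (potentially expensive) evaluations.
#' @return An object of class `"dgp_calibration"` with elements
#'   `final_parameter` (the last midpoint), `final_summary`, `target`,
#'   `converged` (`TRUE` iff the tolerance was met), `trace` (a data frame
#'   with one row per iteration: `iteration`, `lower`, `upper` (the
#'   pre-iteration bracket), `midpoint`, `summary`, `target`, `decision`),
#'   `seed`, and `settings`.
#' @examples
#' res <- bisect_calibrate(function(x) x, target = 0.25,
#'                         bracket = bracket(-10, 10),
#'                         settings = bisection_settings(tolerance = 1e-6))
#' res$trace$midpoint
#' @seealso [find_bracket()], [sequential_calibrate()], [run_scenario()]
#' @export
bisect_calibrate <- function(evaluator, target, bracket,
                             settings = bisection_settings(),
                             seed = 1L, check_endpoints = TRUE) {
  bracket <- as_bracket(bracket)
  stopifnot(inherits(settings, "dgp_bisection_settings"))
  if (!is_scalar_number(target)) spec_error("target must be a finite scalar")
  sgn <- if (settings$direction == "increasing") 1 else -1

  if (isTRUE(check_endpoints)) {
    s_lo <- call_evaluator(evaluator, bracket$lower, substream_seed(seed, 0L))
    s_hi <- call_evaluator(evaluator, bracket$upper, substream_seed(seed, 1L))
    if (!(sgn * s_lo < sgn * target && sgn * target < sgn * s_hi)) {
      bracket_error(sprintf(
        "bracket endpoints do not straddle the target: summary(%g) = %g, summary(%g) = %g, target = %g (direction %s)",
        bracket$lower, s_lo, bracket$upper, s_hi, target, settings$direction),
        lower_summary = s_lo, upper_summary = s_hi)
    }
  }

  lo <- bracket$lower
  hi <- bracket$upper
  n_iter <- settings$max_iterations
  trace <- data.frame(
    iteration = integer(n_iter), lower = numeric(n_iter), upper = numeric(n_iter),
    midpoint = numeric(n_iter), summary = numeric(n_iter),
    target = numeric(n_iter), decision = character(n_iter)
  )
  converged <- FALSE
  k <- 0L
  while (k < n_iter) {
    k <- k + 1L
    mid <- (lo + hi) / 2
    s <- call_evaluator(evaluator, mid, substream_seed(seed, 1L + k))
    if (abs(s - target) <= settings$tolerance) {
      decision <- "stop"
      converged <- TRUE
    } else if (sgn * s < sgn * target) {
      decision <- "go_up"   # summary too low: keep the upper half
    } else {
      decision <- "go_down" # summary too high: keep the lower half
    }
    trace[k, ] <- list(k, lo, hi, mid, s, target, decision)
    if (decision == "go_up") lo <- mid else if (decision == "go_down") hi <- mid
    if (converged) break
  }
  trace <- trace[seq_len(k), , drop = FALSE]

  structure(
    list(final_parameter = trace$midpoint[k],
         final_summary = trace$summary[k],
         target = target,
         converged = converged,
         trace = trace,
         seed = as.integer(seed),
         settings = settings),
    class = "dgp_calibration"
  )
}

#' @export
print.dgp_calibration <- function(x, ...) {
  cat("Bisection calibration\n")
  cat(sprintf("  target:          %g\n", x$target))
  cat(sprintf("  final parameter: %.7g\n", x$final_parameter))
  cat(sprintf("  final summary:   %.7g\n", x$final_summary))
  cat(sprintf("  iterations:      %d (%s)\n", nrow(x$trace),
              if (x$converged) "converged" else "iteration budget exhausted"))
  invisible(x)
}

#' Find a straddling bracket by symmetric geometric expansion
#'
#' Starting from `center +/- initial_halfwidth`, doubles the halfwidth until
#' the endpoint summaries strictly straddle the target, mechanising the
#' grid-search / trial-and-error step of choosing an initial interval.
#'
#' @inheritParams bisect_calibrate
#' @param center Center of the search.
#' @param initial_halfwidth Positive initial halfwidth.
#' @param direction Expected monotonicity of the evaluator.
#' @param max_doublings Attempts allowed beyond the initial halfwidth.
#' @return A [bracket()] whose endpoint summaries straddle `target`.
#'   Fails with a range error if no straddle is found, signalling a target
#'   outside the evaluator's achievable range (e.g. a prevalence target
#'   outside (0, 1)).
#' @export
find_bracket <- function(evaluator, target, center, initial_halfwidth,
                         direction = c("increasing", "decreasing"),
                         max_doublings = 20L, seed = 1L) {
  direction <- match.arg(direction)
  if (!is_scalar_number(initial_halfwidth) || initial_halfwidth <= 0) {
    spec_error("initial_halfwidth must be a positive number")
  }
  sgn <- if (direction == "increasing") 1 else -1
  h <- initial_halfwidth
  for (attempt in 0:max_doublings) {
    lo <- center - h
    hi <- center + h
    s_lo <- call_evaluator(evaluator, lo, substream_seed(seed, 2L * attempt))
    s_hi <- call_evaluator(evaluator, hi, substream_seed(seed, 2L * attempt + 1L))
    if (sgn * s_lo < sgn * target && sgn * target < sgn * s_hi) {
      return(bracket(lo, hi))
    }
    h <- 2 * h
  }
  range_error(sprintf(
    "no straddling bracket within %d doublings of halfwidth %g around %g; target %g may be outside the evaluator's range",
    max_doublings, initial_halfwidth, center, target))
}

#' Write / read a calibration trace as delimited text
#'
#' The trace table has one row per bisection iteration with columns
#' `iteration, lower, upper, midpoint, summary, target, decision`, where
#' `lower`/`upper` are the pre-iteration bracket (so `midpoint` is always
#' their mean).
#'
#' @param x A `"dgp_calibration"` result or its `trace` data frame.
#' @param path File path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns
#'   the trace data frame.
#' @export
write_trace <- function(x, path) {
  trace <- if (inherits(x, "dgp_calibration")) x$trace else x
  stopifnot(is.data.frame(trace))
  utils::write.csv(format(trace, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  trace <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected <- c("iteration", "lower", "upper", "midpoint", "summary", "target", "decision")
  if (!identical(names(trace), expected)) {
    spec_error("not a calibration trace file: unexpected columns")
  }
  trace$iteration <- as.integer(trace$iteration)
  trace
}
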