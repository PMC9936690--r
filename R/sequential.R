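#' Define one problem for sequential (coordinate-wise) calibration
#'
#' A calibration problem names one scalar parameter of a shared
#' data-generating process, the target its summary must attain, and the
#' evaluator that measures that summary given the *full* named parameter
#' set. [sequential_calibrate()] cycles through a list of such problems,
#' bisecting each parameter with the others frozen.
#'
#' @param name Name of the parameter this problem calibrates (must be
#'   unique across the problem list).
#' @param evaluator `function(params, seed)` where `params` is the named
#'   list of *all* problems' current parameter values; returns the scalar
#'   summary for this problem.
#' @param target Target summary value.
#' @param bracket Initial [bracket()] for this parameter.
#' @param settings [bisection_settings()] for this parameter (its
#'   `tolerance` is also the problem's joint-convergence tolerance).
#' @return An object of class `"dgp_calibration_problem"`.
#' @export
calibration_problem <- function(name, evaluator, target, bracket,
                                settings = bisection_settings()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    spec_error("problem name must be a nonempty string")
  }
  stopifnot(is.function(evaluator), inherits(settings, "dgp_bisection_settings"))
  structure(
    list(name = name, evaluator = evaluator, target = target,
         bracket = as_bracket(bracket), settings = settings),
    class = "dgp_calibration_problem"
  )
}

#' Calibrate several parameters of one data-generating process sequentially
#'
#' Cycles through the problems, re-running [bisect_calibrate()] for each
#' parameter with all the other parameters frozen at their current values,
#' and repeats the sweep until every summary is simultaneously within its
#' problem's tolerance or `outer_max` sweeps elapse. Repeating the sweep is
#' necessary because calibrating a later parameter (say a coefficient
#' scale, which moves the outcome prevalence) perturbs the summaries of
#' earlier ones.
#'
#' Joint convergence is declared by re-evaluating every problem's summary
#' at the post-sweep parameter values, so the flag reflects the summaries
#' of the *final* parameter set, not mid-sweep values.
#'
#' @param problems List of [calibration_problem()]s with distinct names.
#' @param outer_max Maximum number of sweeps through the problem list.
#' @param seed Integer base seed; each bisection run and each joint check
#'   gets its own substream.
#' @param initial Optional named list of starting parameter values;
#'   defaults to each problem's bracket midpoint.
#' @return An object of class `"dgp_sequential_calibration"`: `parameters`
#'   (final named values), `summaries` (final joint re-evaluation),
#'   `targets`, `joint_converged`, `sweeps`, and `results` (the last
#'   sweep's per-problem `"dgp_calibration"` objects).
#' @export
sequential_calibrate <- function(problems, outer_max = 5L, seed = 1L,
                                 initial = NULL) {
  if (length(problems) < 1L) spec_error("at least one calibration problem is required")
  ok <- vapply(problems, inherits, logical(1), "dgp_calibration_problem")
  if (!all(ok)) spec_error("problems must be calibration_problem() objects")
  nms <- vapply(problems, `[[`, character(1), "name")
  if (anyDuplicated(nms)) spec_error("problem parameter names must be distinct")

  params <- lapply(problems, function(p) (p$bracket$lower + p$bracket$upper) / 2)
  names(params) <- nms
  if (!is.null(initial)) params[names(initial)] <- initial

  results <- vector("list", length(problems))
  names(results) <- nms
  joint_converged <- FALSE
  sweep <- 0L
  summaries <- rep(NA_real_, length(problems))
  names(summaries) <- nms

  while (sweep < outer_max && !joint_converged) {
    sweep <- sweep + 1L
    for (j in seq_along(problems)) {
      pb <- problems[[j]]
      frozen <- params
      wrapped <- function(x, eval_seed) {
        frozen[[pb$name]] <- x
        pb$evaluator(frozen, eval_seed)
      }
      res <- tryCatch(
        bisect_calibrate(wrapped, pb$target, pb$bracket, pb$settings,
                         seed = substream_seed(seed, 1000L * sweep + j)),
        dgpbisect_error = function(e) {
          e$message <- sprintf("sweep %d, problem '%s': %s", sweep, pb$name, e$message)
          stop(e)
        })
      params[[pb$name]] <- res$final_parameter
      results[[j]] <- res
    }
    # joint check at the final parameter set of this sweep
    for (j in seq_along(problems)) {
      summaries[j] <- call_evaluator(
        function(x, s) problems[[j]]$evaluator(params, s),
        params[[nms[j]]], substream_seed(seed, 1000L * sweep + 500L + j))
    }
    tolerances <- vapply(problems, function(p) p$settings$tolerance, numeric(1))
    targets <- vapply(problems, `[[`, numeric(1), "target")
    joint_converged <- all(abs(summaries - targets) <= tolerances)
  }

  structure(
    list(parameters = unlist(params),
         summaries = summaries,
         targets = vapply(problems, `[[`, numeric(1), "target"),
         joint_converged = joint_converged,
         sweeps = sweep,
         results = results,
         seed = as.integer(seed)),
    class = "dgp_sequential_calibration"
  )
}

#' @export
print.dgp_sequential_calibration <- function(x, ...) {
  cat(sprintf("Sequential calibration: %d sweep(s), %s\n", x$sweeps,
              if (x$joint_converged) "jointly converged" else "not jointly converged"))
  for (nm in names(x$parameters)) {
    cat(sprintf("  %s = %.7g (summary %.7g, target %g)\n",
                nm, x$parameters[[nm]], x$summaries[[nm]], x$targets[[nm]]))
  }
  invisible(x)
}
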