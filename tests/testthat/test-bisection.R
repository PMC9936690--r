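test_that("a deterministic identity evaluator forces the dyadic midpoint path", {
  res <- bisect_calibrate(function(x) x, target = 0.25,
                          bracket = bracket(-10, 10),
                          settings = bisection_settings(tolerance = 1e-6,
                                                        max_iterations = 40))
  expect_identical(res$trace$midpoint[1:6], c(0, 5, 2.5, 1.25, 0.625, 0.3125))
  expect_true(res$converged)
  expect_lt(abs(res$final_parameter - 0.25), 1e-5)
  expect_equal(res$final_summary, res$final_parameter)
})

test_that("every bisection halves the bracket exactly and stays contained", {
  evaluators <- list(
    function(x, seed) plogis(x) + withr::with_seed(seed, rnorm(1, 0, 0.01)),
    function(x, seed) x^3,
    function(x, seed) exp(x / 3)
  )
  targets <- c(0.4, 2, 1.7)
  for (i in seq_along(evaluators)) {
    res <- bisect_calibrate(evaluators[[i]], targets[i], bracket(-10, 10),
                            bisection_settings(tolerance = 0, max_iterations = 16),
                            seed = 100 + i, check_endpoints = FALSE)
    tr <- res$trace
    # reconstruct post-iteration brackets from the decisions
    lo <- tr$lower[1]; hi <- tr$upper[1]
    for (k in seq_len(nrow(tr))) {
      expect_identical(tr$lower[k], lo)
      expect_identical(tr$upper[k], hi)
      expect_identical(tr$midpoint[k], (lo + hi) / 2)
      w_before <- hi - lo
      if (tr$decision[k] == "go_up") lo <- tr$midpoint[k] else hi <- tr$midpoint[k]
      expect_identical(hi - lo, w_before / 2)         # exact halving
      expect_true(lo >= -10 && hi <= 10)              # containment
      expect_true(tr$midpoint[k] > -10 && tr$midpoint[k] < 10)
    }
    expect_identical(hi - lo, 20 / 2^nrow(tr))        # width after K iterations
  }
})

test_that("deterministic monotone evaluators invert the target within width/2^K", {
  cases <- list(
    list(f = function(x) plogis(x), target = 0.3),
    list(f = function(x) x^3 + x, target = 5),
    list(f = function(x) exp(x / 2), target = 3)
  )
  for (K in c(20L, 30L)) {
    for (cs in cases) {
      res <- bisect_calibrate(cs$f, cs$target, bracket(-10, 10),
                              bisection_settings(tolerance = 0, max_iterations = K))
      # independent oracle: exhaustive fine-grid root bracketing
      grid <- seq(-10, 10, length.out = 200001)
      root <- grid[which.min(abs(vapply(grid, cs$f, numeric(1)) - cs$target))]
      expect_lt(abs(res$final_parameter - root), 20 / 2^K + 1e-4)
    }
  }
})

test_that("decreasing evaluators are bisected in natural units", {
  res <- bisect_calibrate(function(x) 1 - 2 * x, target = 0.5, bracket(-10, 10),
                          bisection_settings(tolerance = 1e-8, max_iterations = 50,
                                             direction = "decreasing"))
  expect_lt(abs(res$final_parameter - 0.25), 1e-6)
  # trace keeps the summary on its natural (unnegated) scale
  expect_equal(res$trace$summary[1], 1 - 2 * res$trace$midpoint[1])
})

test_that("an exact hit on the target stops immediately as converged", {
  res <- bisect_calibrate(function(x) x, target = 0, bracket(-10, 10),
                          bisection_settings(tolerance = 0, max_iterations = 10))
  expect_identical(nrow(res$trace), 1L)
  expect_true(res$converged)
  expect_identical(res$trace$decision, "stop")
})

test_that("trace decisions replay to the recorded midpoints", {
  res <- bisect_calibrate(function(x, seed) plogis(x + withr::with_seed(seed, rnorm(1, 0, 0.2))),
                          target = 0.35, bracket(-10, 10),
                          bisection_settings(tolerance = 0, max_iterations = 14),
                          seed = 42, check_endpoints = FALSE)
  tr <- res$trace
  lo <- -10; hi <- 10
  for (k in seq_len(nrow(tr))) {
    expect_identical(tr$midpoint[k], (lo + hi) / 2)
    # the decision must be consistent with the recorded summary and target
    if (tr$decision[k] == "go_up") {
      expect_lt(tr$summary[k], tr$target[k])
      lo <- tr$midpoint[k]
    } else if (tr$decision[k] == "go_down") {
      expect_gt(tr$summary[k], tr$target[k])
      hi <- tr$midpoint[k]
    }
  }
})

test_that("bad brackets and bad evaluators raise classed errors", {
  expect_error(bracket(3, 3), class = "dgpbisect_spec_error")
  expect_error(bracket(1, Inf), class = "dgpbisect_spec_error")
  err <- tryCatch(
    bisect_calibrate(function(x) plogis(x), target = 2, bracket(-5, 5)),
    dgpbisect_bracket_error = function(e) e)
  expect_s3_class(err, "dgpbisect_bracket_error")
  expect_match(conditionMessage(err), "summary\\(-5\\).*summary\\(5\\)")
  expect_error(
    bisect_calibrate(function(x) NaN, target = 0, bracket(-1, 1)),
    class = "dgpbisect_eval_error")
})

test_that("find_bracket expands geometrically and flags unattainable targets", {
  br <- find_bracket(function(x) x, target = 20, center = 0,
                     initial_halfwidth = 10, max_doublings = 3)
  expect_identical(br$upper, 40)
  expect_identical(br$lower, -40)

  br2 <- find_bracket(function(x) plogis(x), target = 0.5, center = 0,
                      initial_halfwidth = 1)
  expect_identical(c(br2$lower, br2$upper), c(-1, 1))

  expect_error(
    find_bracket(function(x) plogis(x), target = -0.2, center = 0,
                 initial_halfwidth = 1, max_doublings = 5),
    class = "dgpbisect_range_error")
})

test_that("trace files round-trip exactly through delimited text", {
  res <- bisect_calibrate(function(x, seed) plogis(x / 3 + withr::with_seed(seed, rnorm(1, 0, 0.05))),
                          target = 0.6, bracket(-10, 10),
                          bisection_settings(tolerance = 1e-4, max_iterations = 20),
                          seed = 9, check_endpoints = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(res, path)
  header <- readLines(path, n = 1)
  expect_identical(header, "iteration,lower,upper,midpoint,summary,target,decision")
  back <- read_trace(path)
  expect_equal(back, res$trace, tolerance = 0)
})
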