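small_cov <- covariate_spec(5, 5, 0.5, 2e4)

test_that("out-of-range targets fail validation before any simulation", {
  expect_error(
    scenario_config("prevalence", small_cov, logistic_spec(0, std_beta),
                    target_value = 1.5, bracket = bracket(-10, 10)),
    class = "dgpbisect_spec_error")
  expect_error(
    scenario_config("relative_risk", small_cov, logistic_spec(0, std_beta),
                    target_value = -0.2, bracket = bracket(-10, 10)),
    class = "dgpbisect_spec_error")
  expect_error(
    scenario_config("c_statistic", small_cov, logistic_spec(0, std_beta),
                    target_value = 0, bracket = bracket(0, 10)),
    class = "dgpbisect_spec_error")
  expect_error(
    scenario_config("prevalence", small_cov, logistic_spec(0, c(1, 2)),
                    target_value = 0.1, bracket = bracket(-10, 10)),
    class = "dgpbisect_spec_error")
})

test_that("the shipped scenario configs carry the reference parameterisation", {
  sc <- default_scenarios(population_size = 1e4, seed = 1)
  expect_named(sc, c("prevalence", "relative_risk", "risk_difference",
                     "c_statistic", "marginal_hazard_ratio", "joint"))
  expect_equal(exp(sc$prevalence$outcome_model$coefficients),
               rep(c(1.25, 1.5, 1.75, 2, 2.5), 2), tolerance = 1e-12)
  expect_equal(exp(sc$relative_risk$treatment_model$coefficients),
               rep(c(1.1, 2, 3, 1.5, 1.5), 2), tolerance = 1e-12)
  expect_identical(sc$relative_risk$target_value, 0.80)
  expect_identical(c(sc$relative_risk$bracket$lower, sc$relative_risk$bracket$upper),
                   c(-10, 10))
  expect_identical(c(sc$c_statistic$bracket$lower, sc$c_statistic$bracket$upper),
                   c(0, 10))
  expect_s3_class(sc$marginal_hazard_ratio$outcome_model, "dgp_survival_spec")
  for (cfg in sc) expect_s3_class(cfg, "dgp_scenario_config")
})

test_that("identical configs and seeds give byte-identical trace files", {
  cfg <- scenario_config("prevalence", small_cov, logistic_spec(0, std_beta),
                         target_value = 0.10, bracket = bracket(-10, 10),
                         settings = bisection_settings(tolerance = 0.004,
                                                       max_iterations = 20),
                         seed = 23)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  r1 <- run_scenario(cfg, trace_file = f1)
  r2 <- run_scenario(cfg, trace_file = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(r1$final_parameter, r2$final_parameter)
  # round-trip reconstructs the in-memory trace
  expect_equal(read_trace(f1), r1$trace, tolerance = 0)
  expect_true(r1$converged)
  expect_lt(abs(r1$final_summary - 0.10), 0.004)
})

test_that("the relative-risk recipe leaves the control arm at its calibrated prevalence", {
  cov1e5 <- covariate_spec(5, 5, 0.5, 1e5)
  sc <- default_scenarios(population_size = 1e5, seed = 29)
  cfg <- sc$relative_risk
  pop <- generate_superpopulation(cov1e5, seed = cfg$seed)
  # gamma does not enter the Z = 0 arm, whatever its calibrated value
  for (gamma in c(-0.3, -1, 0.5)) {
    spec <- cfg$outcome_model
    spec$treatment_log_or <- gamma
    po <- potential_binary_outcomes(pop, spec, seed = 31)
    expect_lt(abs(empirical_prevalence(po$y0) - 0.10), 0.005)
  }
})

test_that("flat config lists build validated scenario configs", {
  raw <- list(target = "relative_risk", target_value = 0.8,
              bracket = c(-10, 10), tolerance = 0.01, max_iterations = 12,
              population_size = 5000, seed = 3,
              outcome_coefficients = as.list(std_beta),
              outcome_intercept = -4.367676,
              treatment_coefficients = as.list(std_alpha),
              treatment_intercept = -3.31749)
  cfg <- scenario_config_from_list(raw)
  expect_identical(cfg$scenario, "relative_risk")
  expect_identical(cfg$outcome_model$intercept, -4.367676)
  expect_identical(cfg$settings$tolerance, 0.01)
  expect_error(scenario_config_from_list(c(raw, list(bogus_key = 1))),
               class = "dgpbisect_spec_error")
  expect_error(scenario_config_from_list(raw[names(raw) != "target_value"]),
               class = "dgpbisect_spec_error")
})

test_that("the command-line wrapper runs a scenario and honours exit codes", {
  skip_if_not_installed("optparse")
  skip_if_not_installed("yaml")
  script <- system.file("cli", "calibrate.R", package = "dgpbisect")
  skip_if(script == "", "CLI script not installed")
  cfg_file <- withr::local_tempfile(fileext = ".yaml")
  trace_file <- withr::local_tempfile(fileext = ".csv")
  result_file <- withr::local_tempfile(fileext = ".txt")
  yaml::write_yaml(list(target = "prevalence", target_value = 0.2,
                        bracket = c(-10, 10), tolerance = 0.01,
                        max_iterations = 15, population_size = 5000,
                        outcome_coefficients = as.list(round(std_beta, 6))),
                   cfg_file)
  # make sure the child process sees the library this package is loaded from
  libs <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  status <- system2("Rscript", c(script, "--config", cfg_file, "--seed", "4",
                                 "--trace-out", trace_file,
                                 "--result-out", result_file),
                    stdout = TRUE, stderr = FALSE, env = libs)
  expect_identical(attr(status, "status"), NULL)  # exit code 0
  tr <- read_trace(trace_file)
  expect_gt(nrow(tr), 0)
  expect_true(any(grepl("^final_parameter:", readLines(result_file))))

  # validation failure maps to exit code 4
  yaml::write_yaml(list(target = "prevalence", target_value = 1.5,
                        outcome_coefficients = as.list(round(std_beta, 6))),
                   cfg_file)
  bad <- suppressWarnings(system2("Rscript", c(script, "--config", cfg_file),
                                  stdout = TRUE, stderr = FALSE, env = libs))
  expect_identical(attr(bad, "status"), 4L)
})
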