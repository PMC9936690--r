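#' Specification of the baseline-covariate distribution
#'
#' Describes the covariate block of the super-population: a set of
#' independent standard-normal columns followed by a set of independent
#' Bernoulli columns. Other covariate distributions can be supplied to
#' [generate_superpopulation()] via its `column_generator` hook; the
#' bisection machinery is agnostic to the covariate distribution.
#'
#' @param n_continuous Number of standard-normal covariates.
#' @param n_binary Number of Bernoulli covariates.
#' @param binary_prob Success probability of the Bernoulli covariates,
#'   in (0, 1).
#' @param population_size Number of subjects `N` in the super-population.
#'   Large values (the default used throughout is 1e6) make empirical
#'   summaries approximate population quantities.
#' @return An object of class `"dgp_covariate_spec"`.
#' @export
covariate_spec <- function(n_continuous = 5L, n_binary = 5L,
                           binary_prob = 0.5, population_size = 1e6) {
  if (!is_scalar_number(n_continuous) || n_continuous < 0 ||
      !is_scalar_number(n_binary) || n_binary < 0) {
    spec_error("covariate counts must be nonnegative integers")
  }
  if (n_continuous + n_binary < 1) {
    spec_error("at least one covariate is required")
  }
  if (!is_scalar_number(binary_prob) || binary_prob <= 0 || binary_prob >= 1) {
    spec_error("binary_prob must lie strictly in (0, 1)")
  }
  if (!is_scalar_number(population_size) || population_size < 1) {
    spec_error("population_size must be a positive integer")
  }
  structure(
    list(n_continuous = as.integer(n_continuous),
         n_binary = as.integer(n_binary),
         binary_prob = binary_prob,
         population_size = as.integer(population_size)),
    class = "dgp_covariate_spec"
  )
}

#' Generate the super-population of baseline covariates
#'
#' Simulates the `N x p` covariate matrix used by every calibration
#' scenario. Covariates are generated once per calibration run and frozen
#' across bisection iterations; only outcomes are re-simulated at each
#' midpoint, so covariate noise never enters the evaluator.
#'
#' @param spec A [covariate_spec()].
#' @param seed Integer seed; identical `(spec, seed)` pairs yield
#'   bitwise-identical matrices.
#' @param column_generator Optional hook replacing the default
#'   normal + Bernoulli sampler: a `function(n, spec)` returning an
#'   `n x (n_continuous + n_binary)` numeric matrix, called inside the
#'   seeded RNG scope.
#' @return An object of class `"dgp_superpopulation"`: a list with `values`
#'   (the `N x p` matrix) and `column_roles` (`"continuous"`/`"binary"`
#'   labels).
#' @export
generate_superpopulation <- function(spec, seed = 1L, column_generator = NULL) {
  stopifnot(inherits(spec, "dgp_covariate_spec"))
  n <- spec$population_size
  p <- spec$n_continuous + spec$n_binary
  roles <- rep(c("continuous", "binary"), c(spec$n_continuous, spec$n_binary))
  values <- withr::with_seed(as.integer(seed), {
    if (is.null(column_generator)) {
      m <- matrix(0, nrow = n, ncol = p)
      if (spec$n_continuous > 0) {
        m[, seq_len(spec$n_continuous)] <- stats::rnorm(n * spec$n_continuous)
      }
      if (spec$n_binary > 0) {
        m[, spec$n_continuous + seq_len(spec$n_binary)] <-
          stats::rbinom(n * spec$n_binary, 1L, spec$binary_prob)
      }
      m
    } else {
      m <- column_generator(n, spec)
      if (!is.matrix(m) || nrow(m) != n || ncol(m) != p) {
        spec_error("column_generator must return an N x p numeric matrix")
      }
      storage.mode(m) <- "double"
      m
    }
  })
  colnames(values) <- paste0("x", seq_len(p))
  structure(
    list(values = values, column_roles = roles, spec = spec, seed = as.integer(seed)),
    class = "dgp_superpopulation"
  )
}

#' @export
print.dgp_superpopulation <- function(x, ...) {
  cat(sprintf("Super-population: %d subjects, %d covariates (%d continuous, %d binary)\n",
              nrow(x$values), ncol(x$values),
              sum(x$column_roles == "continuous"), sum(x$column_roles == "binary")))
  invisible(x)
}

#' Export a super-population as delimited text
#'
#' Writes the covariate matrix with a header row naming each column by its
#' role (`continuous1, ..., binary1, ...`).
#'
#' @param population A `"dgp_superpopulation"`.
#' @param path File path.
#' @export
write_superpopulation <- function(population, path) {
  stopifnot(inherits(population, "dgp_superpopulation"))
  m <- population$values
  idx <- stats::ave(seq_along(population$column_roles), population$column_roles,
                    FUN = seq_along)
  colnames(m) <- paste0(population$column_roles, idx)
  utils::write.csv(m, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
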