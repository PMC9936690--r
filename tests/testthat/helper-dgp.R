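# Shared fixtures and independent oracles, all built in code.

std_beta <- rep(log(c(1.25, 1.5, 1.75, 2, 2.5)), 2)
std_alpha <- rep(log(c(1.1, 2, 3, 1.5, 1.5)), 2)

make_pop <- function(n, seed = 1L) {
  generate_superpopulation(covariate_spec(5L, 5L, 0.5, n), seed = seed)
}

# Wrap a fixed covariate matrix as a super-population (for closed-form
# oracle tests); roles follow the spec's continuous-then-binary layout.
pop_from_matrix <- function(m, n_continuous = ncol(m), n_binary = 0L) {
  spec <- covariate_spec(n_continuous, n_binary, 0.5, nrow(m))
  generate_superpopulation(spec, seed = 1L,
                           column_generator = function(n, s) m)
}

# O(n^2) pairwise-enumeration concordance oracle, ties counted one-half.
c_statistic_bruteforce <- function(scores, outcomes) {
  s1 <- scores[outcomes == 1]
  s0 <- scores[outcomes == 0]
  total <- 0
  for (a in s1) total <- total + sum(a > s0) + 0.5 * sum(a == s0)
  total / (length(s1) * length(s0))
}

# Explicit Breslow partial log-likelihood, written independently of the
# package's risk-set bookkeeping: loop over event times.
cox_loglik_bruteforce <- function(b, times, group, event = rep(1, length(times))) {
  ll <- 0
  for (i in which(event == 1)) {
    at_risk <- times >= times[i]
    ll <- ll + b * group[i] - log(sum(exp(b * group[at_risk])))
  }
  ll
}

# Maximization of the brute-force partial likelihood: coarse grid, then
# golden-section refinement inside the best cell.
cox_mle_grid <- function(times, group, lim = 6) {
  grid <- seq(-lim, lim, by = 0.01)
  ll <- vapply(grid, cox_loglik_bruteforce, numeric(1), times, group)
  best <- grid[which.max(ll)]
  stats::optimize(cox_loglik_bruteforce, c(best - 0.02, best + 0.02),
                  times = times, group = group,
                  maximum = TRUE, tol = 1e-10)$maximum
}
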