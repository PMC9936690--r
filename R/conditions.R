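# Classed conditions so callers (and the CLI) can map failures to exit codes.

dgp_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "dgpbisect_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

spec_error    <- function(message, ...) dgp_error("dgpbisect_spec_error", message, ...)
bracket_error <- function(message, ...) dgp_error("dgpbisect_bracket_error", message, ...)
range_error   <- function(message, ...) dgp_error("dgpbisect_range_error", message, ...)
eval_error    <- function(message, ...) dgp_error("dgpbisect_eval_error", message, ...)
fit_error     <- function(message, ...) dgp_error("dgpbisect_fit_error", message, ...)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Evaluations are seeded with (seed + offset) folded into the 32-bit range
# set.seed() accepts.
substream_seed <- function(seed, offset) {
  as.integer((as.double(seed) + as.double(offset)) %% 2147483647)
}

inv_logit <- function(x) stats::plogis(x)
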