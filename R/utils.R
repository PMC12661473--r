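#' @keywords internal
"_PACKAGE"

# Abort with a classed condition so callers/tests can match on error class.
stop_lny <- function(msg, class = "lnyield_error", ...) {
  stop(structure(
    class = c(class, "lnyield_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Derive a per-stream seed from a global seed; reduced modulo 2^31 - 1 while
# still a double (exact below 2^53), so the result is a valid R integer seed
# for any input seed.
derive_seed <- function(seed, stream) {
  as.integer(((as.double(seed) %% 1000003) * 48271 + stream * 9973) %% 2147483647)
}

# Truncated normal draw by inverse-CDF (exact for the modest truncation used
# for patient age).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

is_count <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == round(x))
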