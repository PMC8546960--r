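#' @keywords internal
"_PACKAGE"

# internal argument checks -----------------------------------------------

stop_if <- function(cond, ...) {
  if (cond) stop(sprintf(...), call. = FALSE)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  stop_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
          "'%s' must be a single finite number", name)
  if (strict_lower) stop_if(x <= lower, "'%s' must be > %g", name, lower)
  else stop_if(x < lower, "'%s' must be >= %g", name, lower)
  if (strict_upper) stop_if(x >= upper, "'%s' must be < %g", name, upper)
  else stop_if(x > upper, "'%s' must be <= %g", name, upper)
  invisible(x)
}

# Derive a deterministic sub-seed for a named random stream from a master
# seed, so that adding one data modality never perturbs the draws of another.
# Kept strictly below 2^31 - 1 (R integers are 32-bit).
sub_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 997) %% 2147483629)
}

# lognormal multiplicative noise with mean 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}
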