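#' @keywords internal
"_PACKAGE"

# Deterministic fan-out of one user-facing seed into independent child
# seeds, one per random stream. Keeps every derived seed inside the 32-bit
# integer range R requires.
fan_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  seed <- as.integer(seed)
  (abs(seed) %% 1000003L) * 2001L + 7L * seq_len(n)
}

# Multiplicative lognormal noise with unit mean and given coefficient of
# variation; cv = 0 returns 1 exactly (no sampling, keeps streams aligned).
lnorm_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  if (strict_lower && x <= lower)
    stop("'", name, "' must be > ", lower, call. = FALSE)
  if (!strict_lower && x < lower)
    stop("'", name, "' must be >= ", lower, call. = FALSE)
  if (x > upper)
    stop("'", name, "' must be <= ", upper, call. = FALSE)
  invisible(x)
}
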