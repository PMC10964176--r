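#' Round half away from zero
#'
#' Conventional "round half up" rounding used when reporting percentages,
#' as opposed to [base::round()]'s round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(96.5)   # 97, where round(96.5) gives 96
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Derive a 32-bit-safe child seed from a master seed and a unit index, so
# each participant (or PSA stream) has its own reproducible RNG stream and
# adding units never perturbs existing ones.
child_seed <- function(seed, id) {
  as.integer((as.double(seed) * 48271 + as.double(id) * 16807) %% 2147483647)
}

# Run code under a temporary RNG state restored on exit.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Truncated normal draw by inverse-CDF; vectorised over n.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    return(rep(min(max(mean, lower), upper), n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
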