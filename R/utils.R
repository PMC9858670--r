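# Evaluate expr under a local RNG seed without disturbing the caller's RNG
# state; a NULL seed just evaluates expr.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

#' Derive a child seed from a master seed
#'
#' One master seed fans out to per-component seeds so each stage of a
#' simulation is independently reproducible.  The scheme is a fixed affine
#' map modulo the largest 32-bit signed prime:
#' `child = (seed * 1000003 + k) mod (2^31 - 1)`.
#'
#' @param seed master integer seed.
#' @param k child index (non-negative integer).
#' @export
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000003 + k) %% 2147483647)
}
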