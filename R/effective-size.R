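#' Female effective population size from theta
#'
#' For a haploid, maternally inherited locus the population mutation
#' parameter satisfies \eqn{\theta = 2 N_{ef} \mu L} when \eqn{\theta} is
#' expressed per sequence and \eqn{\mu} per site per generation, so
#' \deqn{N_{ef}(\mu) = \frac{\theta / L}{2\mu}.}
#' Evaluating at the two ends of a mutation-rate credible interval gives a
#' corresponding interval of effective sizes; the lower mutation rate
#' yields the larger \eqn{N_{ef}}.
#'
#' @param theta_per_sequence a theta estimate on the per-sequence scale
#'   (from [watterson_theta()], [mean_pairwise_differences()] or
#'   [ewens_theta()]); pass the unrounded value.
#' @param L sequence length (sites) used for per-site scaling.
#' @param mu_low,mu_high per-site per-generation mutation rate bounds,
#'   `0 < mu_low <= mu_high`.
#' @param theta_source label recording which estimator theta came from.
#' @return an object of class `ne_estimate`: list with the inputs plus
#'   `ne_at_mu_low` and `ne_at_mu_high` (unrounded; the print method rounds
#'   to whole females).
#' @examples
#' th <- ewens_theta(29, 8)
#' female_effective_size(th, 15460, 1.85e-7, 3e-7)  # about 577 to 356
#' @export
female_effective_size <- function(theta_per_sequence, L, mu_low, mu_high,
                                  theta_source = c("theta_K", "theta_pi", "theta_S")) {
  theta_source <- match.arg(theta_source)
  stopifnot(theta_per_sequence >= 0, L > 0, mu_low > 0, mu_high >= mu_low)
  per_site <- theta_per_sequence / L
  structure(list(theta_source = theta_source,
                 theta_per_sequence = theta_per_sequence, L = L,
                 mu_low = mu_low, mu_high = mu_high,
                 ne_at_mu_low = per_site / (2 * mu_low),
                 ne_at_mu_high = per_site / (2 * mu_high)),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf(
    "N_ef from %s = %.4g (L = %d): %d females at mu = %.3g, %d at mu = %.3g\n",
    x$theta_source, x$theta_per_sequence, x$L,
    round(x$ne_at_mu_low), x$mu_low,
    round(x$ne_at_mu_high), x$mu_high))
  invisible(x)
}

#' @rdname female_effective_size
#' @param x an `ne_estimate`.
#' @export
as.data.frame.ne_estimate <- function(x, ...) {
  data.frame(theta_source = x$theta_source,
             theta = x$theta_per_sequence, L = x$L,
             mu = c(x$mu_low, x$mu_high),
             ne = c(x$ne_at_mu_low, x$ne_at_mu_high))
}
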