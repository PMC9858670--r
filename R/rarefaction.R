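#' Haplotype accumulation (rarefaction) curves
#'
#' For each permutation of the individuals, counts the cumulative number of
#' distinct haplotypes among the first g individuals, g = 1..n, and reports
#' the mean and spread across permutations.  Individuals are resampled
#' without replacement (classic accumulation).  Following the convention of
#' the rarefaction helpers used in barcoding studies, `se_K` is the
#' standard deviation across permutations, i.e. the ribbon half-width one
#' would plot, not the Monte-Carlo error of the mean.
#'
#' @param assignments character vector mapping individuals to haplotype
#'   labels (e.g. the `assignment` element of [collapse_haplotypes()], or
#'   any vector of labels).
#' @param n_perm number of random permutations (>= 1).
#' @param seed optional integer seed; recorded in the result.
#' @return an object of class `accumulation_curve`: a data frame with
#'   columns `g`, `mean_K`, `se_K`, and attributes `n_perm`, `seed`, `K`.
#' @examples
#' curve <- haplotype_accumulation(c("a", "a", "b"), n_perm = 200, seed = 1)
#' curve$mean_K[3]  # always 2 at g = n
#' @export
haplotype_accumulation <- function(assignments, n_perm = 1000, seed = NULL) {
  n <- length(assignments)
  stopifnot(n >= 1, n_perm >= 1)
  hap <- as.integer(factor(assignments))
  acc <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      ord <- sample.int(n)
      cumsum(!duplicated(hap[ord]))
    }, integer(n))
  })                                     # n x n_perm
  acc <- matrix(acc, nrow = n)
  out <- data.frame(g = seq_len(n),
                    mean_K = rowMeans(acc),
                    se_K = apply(acc, 1L, stats::sd))
  out$se_K[n] <- 0  # endpoint is deterministic
  structure(out, n_perm = n_perm, seed = seed, K = max(hap),
            class = c("accumulation_curve", "data.frame"))
}

#' Exact expected accumulation curve
#'
#' Closed-form expectation of the number of distinct haplotypes in a random
#' subsample of size g drawn without replacement (the hypergeometric
#' rarefaction formula):
#' \deqn{E[K_g] = \sum_h \left[1 - \binom{n - c_h}{g} \Big/ \binom{n}{g}\right]}
#' with \eqn{\binom{a}{b} = 0} when \eqn{a < b}.  Serves as an independent
#' oracle for the permutation estimate of [haplotype_accumulation()].
#'
#' @param counts integer vector of per-haplotype counts.
#' @return numeric vector of expectations for g = 1..n.
#' @examples
#' expected_accumulation_exact(c(2, 1))[2]  # 5/3
#' @export
expected_accumulation_exact <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) >= 1, all(counts >= 1))
  n <- sum(counts)
  vapply(seq_len(n), function(g) {
    # lchoose returns -Inf for a < b, so exp() gives the required 0
    sum(1 - exp(lchoose(n - counts, g) - lchoose(n, g)))
  }, numeric(1))
}

#' @export
print.accumulation_curve <- function(x, ...) {
  cat(sprintf("accumulation_curve: n = %d, K = %d, %d permutations\n",
              nrow(x), attr(x, "K"), attr(x, "n_perm")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Plot accumulation curves
#'
#' Draws the mean curve with a mean +/- se ribbon for one or more groups;
#' when several curves are supplied a vertical line marks the smallest
#' group size, beyond which curves are not comparable.
#'
#' @param x an `accumulation_curve` or a named list of them.
#' @param ... passed to [graphics::plot()].
#' @export
plot.accumulation_curve <- function(x, ...) {
  plot_accumulation(list(x), ...)
}

#' @rdname plot.accumulation_curve
#' @param curves named list of `accumulation_curve` objects.
#' @param col colours, one per curve.
#' @export
plot_accumulation <- function(curves, col = seq_along(curves), ...) {
  xmax <- max(vapply(curves, nrow, integer(1)))
  ymax <- max(vapply(curves, function(cv) max(cv$mean_K + cv$se_K), numeric(1)))
  graphics::plot(NULL, xlim = c(1, xmax), ylim = c(1, ymax),
                 xlab = "individuals sampled (g)",
                 ylab = "accumulated haplotypes", ...)
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    graphics::polygon(c(cv$g, rev(cv$g)),
                      c(cv$mean_K + cv$se_K, rev(cv$mean_K - cv$se_K)),
                      col = grDevices::adjustcolor(col[i], alpha.f = 0.2),
                      border = NA)
    graphics::lines(cv$g, cv$mean_K, col = col[i], lwd = 2)
  }
  if (length(curves) > 1L)
    graphics::abline(v = min(vapply(curves, nrow, integer(1))), lty = 2)
  if (!is.null(names(curves)))
    graphics::legend("bottomright", legend = names(curves), col = col, lwd = 2)
  invisible(curves)
}
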