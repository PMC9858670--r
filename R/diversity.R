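#' Haplotype (gene) diversity with sampling variance
#'
#' Unbiased haplotype diversity
#' \deqn{\hat H_d = \frac{n}{n-1}\left(1 - \sum_i \hat p_i^2\right)}
#' with Nei's sampling variance
#' \deqn{V(\hat H_d) = \frac{2}{n(n-1)}\left\{2(n-2)\left[\sum \hat p_i^3 -
#'   \left(\sum \hat p_i^2\right)^2\right] + \sum \hat p_i^2 -
#'   \left(\sum \hat p_i^2\right)^2\right\}}
#' where \eqn{\hat p_i = c_i/n} are observed haplotype frequencies.
#'
#' @param counts integer vector of per-haplotype counts, all >= 1.
#' @return list with elements `Hd`, `sd`, `n`, `K`.
#' @examples
#' haplotype_diversity(c(10, 2, 5))$Hd   # 0.588
#' @export
haplotype_diversity <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L || any(counts < 1))
    stop("counts must be a nonempty vector of positive haplotype counts")
  n <- sum(counts)
  if (n < 2) stop("need at least two individuals (n >= 2)")
  p <- counts / n
  s2 <- sum(p^2)
  s3 <- sum(p^3)
  Hd <- n * (1 - s2) / (n - 1)
  v <- (2 / (n * (n - 1))) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(Hd = Hd, sd = sqrt(max(v, 0)), n = n, K = length(counts))
}

# pairwise mismatch and shared-site counts; returns list(d, len) of n x n
# matrices.  A is coded 1..4, N as 0, so a site contributes to a pair only
# when both codes are positive.
.pair_diff <- function(aln) {
  code <- matrix(match(unclass(aln), c("A", "C", "G", "T"), nomatch = 0L),
                 nrow = nrow(aln))
  n <- nrow(code)
  d <- matrix(0L, n, n)
  len <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) {
    xi <- code[i, ]
    for (j in (i + 1L):n) {
      xj <- code[j, ]
      both <- xi > 0L & xj > 0L
      dij <- sum(xi[both] != xj[both])
      d[i, j] <- d[j, i] <- dij
      len[i, j] <- len[j, i] <- sum(both)
    }
  }
  dimnames(d) <- dimnames(len) <- list(rownames(aln), rownames(aln))
  list(d = d, len = len)
}

#' Theta from mean pairwise differences
#'
#' The average number of nucleotide differences between all \eqn{n(n-1)/2}
#' sequence pairs (an estimator of the population mutation parameter
#' \eqn{\theta} per sequence), with Tajima's variance
#' \deqn{V = \frac{n+1}{3(n-1)}\hat\theta_\pi +
#'   \frac{2(n^2+n+3)}{9n(n-1)}\hat\theta_\pi^2.}
#'
#' Under `deletion = "pairwise"` each pair is compared at the sites
#' non-missing in both (appropriate when low-coverage historical sequences
#' would otherwise collapse the usable length); under `"complete"` only
#' sites with no missing data in any sequence are used.
#'
#' @param aln an [mt_alignment()] with n >= 2 sequences.
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return list with `theta_pi`, `sd`, `n`, and `L_eff`, the mean number of
#'   compared sites per pair (used by [nucleotide_diversity()] for per-site
#'   scaling).
#' @export
mean_pairwise_differences <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  n <- nrow(aln)
  if (n < 2) stop("need at least two sequences")
  if (deletion == "complete") {
    keep <- colSums(unclass(aln) == "N") == 0L
    if (!any(keep)) stop("no complete sites under complete deletion")
    aln <- aln[, keep]
  }
  pd <- .pair_diff(aln)
  ut <- upper.tri(pd$d)
  theta_pi <- mean(pd$d[ut])
  list(theta_pi = theta_pi, sd = theta_pi_sd(theta_pi, n), n = n,
       L_eff = mean(pd$len[ut]))
}

#' @rdname mean_pairwise_differences
#' @param theta_pi mean number of pairwise differences.
#' @param n sample size.
#' @export
theta_pi_sd <- function(theta_pi, n) {
  v <- (n + 1) / (3 * (n - 1)) * theta_pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * theta_pi^2
  sqrt(v)
}

#' Per-site nucleotide diversity
#'
#' Scales the per-sequence mean pairwise difference and its SD by the
#' effective sequence length.
#'
#' @param theta_pi mean pairwise differences (per sequence).
#' @param sd_theta_pi its standard deviation.
#' @param L_eff effective length in sites (> 0).
#' @return list with `pi` and `sd`.
#' @export
nucleotide_diversity <- function(theta_pi, sd_theta_pi, L_eff) {
  stopifnot(L_eff > 0)
  list(pi = theta_pi / L_eff, sd = sd_theta_pi / L_eff)
}

#' Number of segregating (polymorphic) sites
#'
#' @param aln an [mt_alignment()].
#' @param site_policy `"any_two_nonmissing"` counts a site as segregating
#'   when at least two distinct non-missing states are observed;
#'   `"complete_only"` first drops every site with any missing data.
#' @return integer count S.
#' @export
segregating_sites <- function(aln, site_policy = c("any_two_nonmissing", "complete_only")) {
  site_policy <- match.arg(site_policy)
  mat <- unclass(aln)
  if (nrow(mat) < 2) stop("need at least two sequences")
  if (site_policy == "complete_only") {
    mat <- mat[, colSums(mat == "N") == 0L, drop = FALSE]
    if (ncol(mat) == 0L) return(0L)
  }
  seg <- vapply(seq_len(ncol(mat)), function(j) {
    x <- mat[, j]
    x <- x[x != "N"]
    length(x) >= 2L && any(x != x[1L])
  }, logical(1))
  sum(seg)
}

# harmonic numbers a1 = sum 1/i, a2 = sum 1/i^2 over i = 1..n-1
.harmonic <- function(n) {
  i <- seq_len(n - 1L)
  list(a1 = sum(1 / i), a2 = sum(1 / i^2))
}

#' Watterson's theta from segregating sites
#'
#' \eqn{\hat\theta_S = S / a_1} with \eqn{a_1 = \sum_{i=1}^{n-1} 1/i}, and
#' the estimator variance
#' \deqn{V = \frac{\hat\theta_S}{a_1} + \frac{a_2}{a_1^2}\hat\theta_S^2,
#'   \qquad a_2 = \sum_{i=1}^{n-1} 1/i^2.}
#'
#' @param S observed number of segregating sites.
#' @param n sample size (>= 2).
#' @return list with `theta_S`, `sd`, `a1`, `a2`.
#' @examples
#' watterson_theta(41, 19)$theta_S  # 11.73
#' @export
watterson_theta <- function(S, n) {
  stopifnot(n >= 2, S >= 0)
  h <- .harmonic(n)
  theta <- S / h$a1
  v <- theta / h$a1 + h$a2 * theta^2 / h$a1^2
  list(theta_S = theta, sd = sqrt(v), a1 = h$a1, a2 = h$a2)
}

#' Expected number of haplotypes under the Ewens sampling formula
#'
#' \deqn{E[K] = \sum_{i=0}^{n-1} \frac{\theta}{\theta + i}}
#'
#' @param theta scaled mutation parameter (per sequence), >= 0.
#' @param n sample size.
#' @export
ewens_expected_K <- function(theta, n) {
  if (theta == 0) return(1)
  sum(theta / (theta + 0:(n - 1L)))
}

#' Ewens estimator of theta from the number of haplotypes
#'
#' Inverts \eqn{K = E[K](\theta)} (see [ewens_expected_K()]) by bracketed
#' root finding; the expectation is strictly increasing in \eqn{\theta}, so
#' the root is unique.  `K = 1` gives 0.  `K = n` has no finite solution
#' (every individual its own haplotype is the \eqn{\theta \to \infty}
#' limit): `Inf` is returned with attribute `unbounded = TRUE`.
#'
#' @param n sample size (>= 1).
#' @param K observed number of haplotypes, `1 <= K <= n`.
#' @param tol relative convergence tolerance for the root.
#' @return the maximum-likelihood \eqn{\hat\theta_K}.
#' @examples
#' ewens_theta(17, 3)  # 0.77
#' @export
ewens_theta <- function(n, K, tol = 1e-10) {
  stopifnot(n >= 1, K >= 1, K <= n)
  if (K == 1) return(0)
  if (K == n) {
    warning("K = n: theta is unbounded (returned Inf)")
    return(structure(Inf, unbounded = TRUE))
  }
  f <- function(th) ewens_expected_K(th, n) - K
  hi <- 1e6
  while (f(hi) < 0) hi <- hi * 10
  stats::uniroot(f, c(1e-10, hi), tol = tol * K)$root
}

#' Log unsigned Stirling numbers of the first kind
#'
#' Returns \eqn{\log |s(n, k)|} for `k = 1..n`, computed in log space with
#' the recurrence \eqn{|s(n,k)| = |s(n-1,k-1)| + (n-1)|s(n-1,k)|} so that
#' sample sizes in the hundreds do not overflow.
#'
#' @param n a positive integer.
#' @return numeric vector of length `n`.
#' @export
log_stirling1 <- function(n) {
  stopifnot(n >= 1)
  ls <- 0  # n = 1: |s(1,1)| = 1
  if (n == 1) return(ls)
  for (m in 2:n) {
    prev <- ls
    ls <- numeric(m)
    # k = 1: |s(m,1)| = (m-1)!
    ls[1] <- log(m - 1) + prev[1]
    if (m > 2) {
      k <- 2:(m - 1)
      a <- prev[k - 1]                  # |s(m-1, k-1)|
      b <- log(m - 1) + prev[k]         # (m-1) |s(m-1, k)|
      hi2 <- pmax(a, b)
      ls[k] <- hi2 + log1p(exp(pmin(a, b) - hi2))
    }
    ls[m] <- 0  # |s(m,m)| = 1
  }
  ls
}

#' Distribution of the number of haplotypes under the Ewens sampling formula
#'
#' \deqn{P(K = k \mid \theta, n) = \frac{|s(n,k)|\,\theta^k}
#'   {\theta(\theta+1)\cdots(\theta+n-1)}}
#'
#' @param theta scaled mutation parameter (> 0).
#' @param n sample size.
#' @return probability vector over `k = 1..n`.
#' @export
esf_K_pmf <- function(theta, n) {
  stopifnot(theta > 0, n >= 1)
  ls <- log_stirling1(n)
  k <- seq_len(n)
  lp <- ls + k * log(theta) - sum(log(theta + 0:(n - 1L)))
  exp(lp)
}

#' Equal-tail confidence interval for the Ewens theta estimate
#'
#' Inverts the sampling distribution of the number of haplotypes K (see
#' [esf_K_pmf()]): the lower bound solves
#' \eqn{P(K \ge k_{obs} \mid \theta) = (1-level)/2} and the upper bound
#' \eqn{P(K \le k_{obs} \mid \theta) = (1-level)/2}.  With `K = 1` the left
#' tail is degenerate and the lower bound is 0.
#'
#' @inheritParams ewens_theta
#' @param level confidence level (default 0.95).
#' @return numeric vector `c(lo, hi)`.
#' @export
ewens_theta_ci <- function(n, K, level = 0.95) {
  stopifnot(n >= 1, K >= 1, K <= n, level > 0, level < 1)
  alpha <- (1 - level) / 2
  tail_ge <- function(th) sum(esf_K_pmf(th, n)[K:n])         # P(K >= k_obs)
  tail_le <- function(th) sum(esf_K_pmf(th, n)[seq_len(K)])  # P(K <= k_obs)
  lo <- if (K == 1) 0 else {
    stats::uniroot(function(th) tail_ge(th) - alpha,
                   c(1e-12, 1e8), tol = 1e-10)$root
  }
  hi <- if (K == n) {
    warning("K = n: upper confidence bound is unbounded (returned Inf)")
    Inf
  } else {
    hi0 <- 1e6
    while (tail_le(hi0) > alpha) hi0 <- hi0 * 10
    stats::uniroot(function(th) tail_le(th) - alpha,
                   c(1e-12, hi0), tol = 1e-10)$root
  }
  c(lo = lo, hi = hi)
}

#' Per-group diversity summary
#'
#' Assembles, for every group in the assignment, the full set of diversity
#' indices: sample size n, haplotype count K, segregating sites S,
#' haplotype diversity Hd with SD, mean pairwise differences
#' \eqn{\hat\theta_\pi} with Tajima's SD, per-site nucleotide diversity
#' \eqn{\pi} with SD, Watterson's \eqn{\hat\theta_S} with SD, and the Ewens
#' \eqn{\hat\theta_K} with its equal-tail confidence interval.
#'
#' @param aln an [mt_alignment()] containing all individuals.
#' @param groups group assignment (data frame or named vector, see
#'   [collapse_haplotypes()]).
#' @param deletion deletion policy for pairwise differences.
#' @param site_policy site policy for segregating sites.
#' @param missing_policy haplotype-collapsing policy.
#' @param L_eff per-site scaling length; by default the mean pairwise
#'   number of shared non-missing sites within each group (see
#'   [mean_pairwise_differences()]).  Pass a fixed length (e.g. the
#'   alignment length) to override.
#' @param ci_level confidence level for the Ewens interval.
#' @return a data frame with one row per group, carrying the policies used
#'   in attribute `policies`.
#' @export
diversity_summary <- function(aln, groups = NULL,
                              deletion = c("pairwise", "complete"),
                              site_policy = c("any_two_nonmissing", "complete_only"),
                              missing_policy = c("strict", "merge_compatible"),
                              L_eff = NULL, ci_level = 0.95) {
  deletion <- match.arg(deletion)
  site_policy <- match.arg(site_policy)
  missing_policy <- match.arg(missing_policy)

  grp <- if (is.null(groups)) {
    stats::setNames(rep("all", nrow(aln)), rownames(aln))
  } else {
    .group_vector(groups, rownames(aln))
  }
  ht <- collapse_haplotypes(aln, groups = grp, missing_policy = missing_policy)

  rows <- lapply(unique(grp), function(g) {
    sub <- aln[names(grp)[grp == g], ]
    n <- nrow(sub)
    if (n < 2) stop("group '", g, "' has fewer than 2 individuals")
    counts <- haplotype_counts(ht, g)
    hd <- haplotype_diversity(counts)
    mpd <- mean_pairwise_differences(sub, deletion = deletion)
    Leff_g <- if (is.null(L_eff)) mpd$L_eff else L_eff
    pi <- nucleotide_diversity(mpd$theta_pi, mpd$sd, Leff_g)
    S <- segregating_sites(sub, site_policy = site_policy)
    ws <- watterson_theta(S, n)
    K <- length(counts)
    thK <- ewens_theta(n, K)
    ci <- if (is.finite(thK) && K < n) ewens_theta_ci(n, K, ci_level) else c(NA_real_, NA_real_)
    data.frame(group = g, n = n, K = K, S = S,
               Hd = hd$Hd, sd_Hd = hd$sd,
               theta_pi = mpd$theta_pi, sd_theta_pi = mpd$sd,
               pi = pi$pi, sd_pi = pi$sd,
               theta_S = ws$theta_S, sd_theta_S = ws$sd,
               theta_K = as.numeric(thK),
               theta_K_ci_low = ci[1], theta_K_ci_high = ci[2],
               a1 = ws$a1, a2 = ws$a2, L_eff = Leff_g,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "policies") <- list(deletion = deletion, site_policy = site_policy,
                                missing_policy = missing_policy,
                                ci_level = ci_level,
                                version = as.character(utils::packageVersion("mitodiv")))
  out
}
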