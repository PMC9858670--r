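# Independent oracles used across the suite.  These deliberately take the
# slow, literal route (per-site loops, exact integer arithmetic, full
# enumeration) so they share no code with the implementation they check.

# mean pairwise differences by an explicit per-pair, per-site loop
brute_theta_pi <- function(aln) {
  mat <- unclass(aln)
  n <- nrow(mat)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- 0
      for (s in seq_len(ncol(mat))) {
        a <- mat[i, s]; b <- mat[j, s]
        if (a != "N" && b != "N" && a != b) d <- d + 1
      }
      total <- total + d
    }
  }
  total / (n * (n - 1) / 2)
}

# exact unsigned Stirling numbers of the first kind, integer recurrence
exact_stirling1 <- function(n) {
  s <- 1
  if (n == 1) return(s)
  for (m in 2:n) {
    prev <- c(0, s, 0)
    s <- numeric(m)
    for (k in 1:m) s[k] <- prev[k] + (m - 1) * prev[k + 1]
  }
  s
}

# ESF P(K = k | theta, n) from exact Stirling numbers
exact_esf_pmf <- function(theta, n) {
  s <- exact_stirling1(n)
  k <- seq_len(n)
  p <- s * theta^k / prod(theta + 0:(n - 1))
  p
}

# random alignment with optional missing fraction
random_alignment <- function(n, L, miss = 0) {
  mat <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  if (miss > 0) {
    mask <- matrix(runif(n * L) < miss, n, L)
    mat[mask] <- "N"
  }
  mt_alignment(mat, ids = paste0("s", seq_len(n)))
}

# shortest path length between two nodes of a haplotype_network (sum of
# edge weights), via igraph
net_path_length <- function(net, from, to) {
  g <- as_igraph(net)
  igraph::distances(g, v = from, to = to,
                    weights = igraph::E(g)$mutations)[1, 1]
}
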