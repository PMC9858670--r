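#' Sample a haplotype partition from the Ewens sampling formula
#'
#' Hoppe-urn (Chinese restaurant) construction: individual i + 1 founds a
#' new haplotype with probability \eqn{\theta / (\theta + i)}, otherwise
#' joins an existing haplotype with probability proportional to its current
#' count.  The resulting counts follow the Ewens sampling formula — the
#' neutral-model distribution that [ewens_theta()] inverts.
#'
#' @param theta scaled mutation parameter (>= 0); 0 gives a single
#'   haplotype.
#' @param n sample size (>= 1).
#' @param seed optional integer seed.
#' @return integer vector of haplotype counts (in founding order), summing
#'   to n.
#' @export
sample_esf_partition <- function(theta, n, seed = NULL) {
  stopifnot(theta >= 0, n >= 1)
  with_seed(seed, {
    counts <- integer(0)
    for (i in 0:(n - 1L)) {
      if (i == 0L || stats::runif(1) < theta / (theta + i)) {
        counts <- c(counts, 1L)
      } else {
        j <- sample.int(length(counts), 1L, prob = counts)
        counts[j] <- counts[j] + 1L
      }
    }
    counts
  })
}

#' Simulate an alignment under the neutral coalescent with infinite sites
#'
#' Draws a Kingman coalescent genealogy for n lineages (exponential waiting
#' times with rate \eqn{\binom{k}{2}} while k lineages remain), places
#' Poisson(\eqn{\theta/2 \times} branch length) mutations on each branch,
#' and assigns every mutation to a distinct alignment site (the
#' infinite-sites assumption, valid while the expected number of
#' segregating sites is far below L).  Ancestral states are drawn uniformly
#' per site and each mutation substitutes a different base in all
#' descendants of its branch.
#'
#' Expectations under this model: \eqn{E[S] = \theta \sum_{i<n} 1/i} and
#' \eqn{E[\hat\theta_\pi] = \theta}.
#'
#' @param n number of sequences (>= 2).
#' @param theta per-sequence scaled mutation parameter.
#' @param L alignment length in sites.
#' @param seed optional integer seed.
#' @return an [mt_alignment()] of n sequences named `sim1..simN`.
#' @export
coalescent_infinite_sites <- function(n, theta, L, seed = NULL) {
  stopifnot(n >= 2, theta >= 0, L >= 1)
  h <- .harmonic(n)
  if (theta * h$a1 > L / 2)
    stop("expected segregating sites (", round(theta * h$a1, 1),
         ") exceed L/2; increase L")
  with_seed(seed, {
    # active lineages as lists of descendant tip indices
    lineages <- as.list(seq_len(n))
    carriers <- list()  # per mutation: tip index set
    k <- n
    while (k > 1L) {
      t_k <- stats::rexp(1, rate = k * (k - 1) / 2)
      # mutations on each active branch during this interval
      n_mut <- stats::rpois(k, theta / 2 * t_k)
      for (b in which(n_mut > 0L)) {
        carriers <- c(carriers, rep(lineages[b], n_mut[b]))
      }
      pair <- sample.int(k, 2L)
      merged <- c(lineages[[pair[1L]]], lineages[[pair[2L]]])
      lineages[[pair[1L]]] <- merged
      lineages[[pair[2L]]] <- NULL
      k <- k - 1L
    }
    S <- length(carriers)
    if (S > L) stop("realised segregating sites (", S, ") exceed L; increase L")
    bases <- c("A", "C", "G", "T")
    mat <- matrix(sample(bases, L, replace = TRUE), nrow = n, ncol = L,
                  byrow = TRUE)
    if (S > 0L) {
      sites <- sample.int(L, S)
      for (s in seq_len(S)) {
        anc <- mat[1L, sites[s]]
        derived <- sample(setdiff(bases, anc), 1L)
        mat[carriers[[s]], sites[s]] <- derived
      }
    }
    mt_alignment(mat, ids = paste0("sim", seq_len(n)))
  })
}

#' Mask sites as missing, mimicking low-coverage historical sequences
#'
#' Per individual, a uniformly chosen set of `floor(f * L)` sites is set to
#' N.  This emulates the patchy recovery typical of museum-specimen
#' sequencing, where coverage per specimen can range over two orders of
#' magnitude.
#'
#' @param aln an [mt_alignment()].
#' @param per_individual_fractions numeric vector in `[0, 1]`, recycled to
#'   the number of sequences.
#' @param seed optional integer seed.
#' @return the masked alignment.
#' @export
mask_missing <- function(aln, per_individual_fractions, seed = NULL) {
  f <- rep_len(per_individual_fractions, nrow(aln))
  stopifnot(all(f >= 0), all(f <= 1))
  L <- ncol(aln)
  with_seed(seed, {
    mat <- unclass(aln)
    for (i in seq_len(nrow(mat))) {
      k <- floor(f[i] * L)
      if (k > 0L) mat[i, sample.int(L, k)] <- "N"
    }
    mt_alignment(mat, ids = rownames(aln))
  })
}

#' Configuration for a two-epoch simulation
#'
#' Defaults emulate the whole-mitogenome study regime: 19 historical and 29
#' modern sequences of L = 15,460 sites with theta chosen so the expected
#' number of segregating sites at n = 19 is about 41, drift at a female
#' effective size of 350 (about the current number of reproducing females)
#' over 15 generations (roughly five decades at a three-year generation
#' time), and historical missing-data fractions uniform on [0, 0.3].
#'
#' @param theta per-sequence scaled mutation parameter.
#' @param n_hist,n_modern epoch sample sizes.
#' @param n_pool extra simulated lineages representing the unsampled
#'   historical population from which the modern epoch descends.
#' @param L alignment length (sites).
#' @param f_max historical missing fractions are drawn uniformly on
#'   `[0, f_max]`.
#' @param Ne female effective size during the drift phase.
#' @param G number of Wright-Fisher generations of drift.
#' @param seed master seed; fans out to stage seeds via [child_seed()].
#' @export
simulation_config <- function(theta = 11.7, n_hist = 19, n_modern = 29,
                              n_pool = 29, L = 15460, f_max = 0.3,
                              Ne = 350, G = 15, seed = NULL) {
  stopifnot(theta >= 0, n_hist >= 2, n_modern >= 2, n_pool >= 0, L >= 1,
            f_max >= 0, f_max <= 1, Ne >= 1, G >= 0)
  structure(list(theta = theta, n_hist = n_hist, n_modern = n_modern,
                 n_pool = n_pool, L = L, f_max = f_max, Ne = Ne, G = G,
                 seed = seed),
            class = "simulation_config")
}

#' Simulate historical and modern epoch samples with drift between them
#'
#' A haplotype pool is generated once with [coalescent_infinite_sites()] on
#' `n_hist + n_pool` lineages.  The historical sample is the first
#' `n_hist` sequences.  Population haplotype frequencies (from the full
#' pool) are then drifted by Wright-Fisher multinomial resampling at size
#' `Ne` for `G` generations — no new mutations, since the decades spanned
#' are negligible on the mitochondrial mutational timescale — and the
#' modern sample is drawn from the drifted frequencies.  Finally the
#' historical alignment is masked with per-individual missing fractions
#' uniform on `[0, f_max]`.
#'
#' @param config a [simulation_config()].
#' @return list with `historical` and `modern` (both [mt_alignment()]s) and
#'   `groups` (data frame id/group consumable by [diversity_summary()]).
#' @export
simulate_two_epoch <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  seeds <- if (is.null(config$seed)) {
    rep(list(NULL), 4L)
  } else {
    lapply(1:4, function(k) child_seed(config$seed, k))
  }
  n_tot <- config$n_hist + config$n_pool
  pool <- coalescent_infinite_sites(n_tot, config$theta, config$L,
                                    seed = seeds[[1L]])
  hist_aln <- pool[seq_len(config$n_hist), ]
  rownames(hist_aln) <- paste0("hist", seq_len(config$n_hist))

  ht <- collapse_haplotypes(pool)
  freq <- as.numeric(ht$counts[, 1L]) / n_tot

  freq <- with_seed(seeds[[2L]], {
    p <- freq
    for (g in seq_len(config$G)) {
      p <- as.numeric(stats::rmultinom(1L, config$Ne, p)) / config$Ne
    }
    p
  })

  draw <- with_seed(seeds[[3L]], {
    as.numeric(stats::rmultinom(1L, config$n_modern, freq))
  })
  if (sum(draw > 0) == 1L)
    warning("drift left a single haplotype; modern sample is monomorphic")
  hap_idx <- rep(seq_along(draw), draw)
  mod_mat <- ht$haplotypes[hap_idx, , drop = FALSE]
  mod_aln <- mt_alignment(mod_mat, ids = paste0("mod", seq_len(config$n_modern)))

  f <- with_seed(seeds[[4L]], stats::runif(config$n_hist, 0, config$f_max))
  hist_aln <- mask_missing(hist_aln, f,
                           seed = if (is.null(config$seed)) NULL
                                  else child_seed(config$seed, 5L))

  groups <- data.frame(
    id = c(rownames(hist_aln), rownames(mod_aln)),
    group = rep(c("historical", "modern"),
                c(config$n_hist, config$n_modern)),
    stringsAsFactors = FALSE)
  list(historical = hist_aln, modern = mod_aln, groups = groups)
}
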