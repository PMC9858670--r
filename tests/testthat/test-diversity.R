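test_that("haplotype diversity matches published wolf values and edge cases", {
  # counts tallied from the published historical/modern haplotype tables
  expect_equal(round(haplotype_diversity(c(10, 2, 5))$Hd, 3), 0.588)
  expect_equal(round(haplotype_diversity(c(2, 2, 2, 4, 4, 1, 1, 1, 1, 1))$Hd, 3),
               0.912)
  mod <- haplotype_diversity(c(6, 7, 3, 1, 4, 6, 1, 1))
  expect_equal(round(mod$Hd, 3), 0.852)
  expect_equal(round(mod$sd, 3), 0.030)
  expect_equal(haplotype_diversity(7)$Hd, 0)   # monomorphic
  expect_error(haplotype_diversity(integer(0)))
  expect_error(haplotype_diversity(1), "n >= 2")
})

test_that("Hd is bounded in [0, 1] across random count vectors", {
  set.seed(7)
  for (i in 1:50) {
    counts <- sample(1:10, sample(1:8, 1), replace = TRUE)
    if (sum(counts) < 2) next
    h <- haplotype_diversity(counts)
    expect_gte(h$Hd, 0)
    expect_lte(h$Hd, 1)
  }
})

test_that("mean pairwise differences equal the brute-force pair average", {
  # trivial three-pair case: differences 1, 2, 3 average to 2
  aln <- mt_alignment(c(a = "AAAA", b = "AAAT", c = "ATTT"))
  expect_equal(mean_pairwise_differences(aln)$theta_pi, 2)

  set.seed(99)
  for (i in 1:10) {
    aln <- random_alignment(sample(4:12, 1), sample(10:30, 1), miss = 0.15)
    got <- mean_pairwise_differences(aln, deletion = "pairwise")$theta_pi
    expect_equal(got, brute_theta_pi(aln))
  }
})

test_that("Tajima's variance reproduces the published theta_pi SDs", {
  expect_equal(round(theta_pi_sd(12.74, 29), 2), 6.58)
  expect_equal(round(theta_pi_sd(2.43, 17), 2), 1.55)
  expect_equal(round(theta_pi_sd(2.15, 27), 2), 1.37)
  expect_equal(round(theta_pi_sd(12.83, 19), 2), 6.76)
})

test_that("nucleotide diversity is theta_pi scaled per site", {
  got <- nucleotide_diversity(12.74, 6.58, 15460)
  expect_equal(signif(got$pi, 2), 8.2e-4)
  expect_equal(signif(got$sd, 2), 4.3e-4)
  expect_equal(nucleotide_diversity(0, 0, 425), list(pi = 0, sd = 0))
  expect_equal(signif(nucleotide_diversity(2.15, 1.37, 425)$pi, 3), 5.06e-3)
})

test_that("segregating sites respect site policies and missing data", {
  same <- mt_alignment(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_equal(segregating_sites(same), 0)
  two <- mt_alignment(c(a = "ACGTACGT", b = "TCGAACGA"))
  expect_equal(segregating_sites(two), 3)
  # with one N, site 1 has a single non-missing state and no longer counts
  mis <- mt_alignment(c(a = "ACGT", b = "ACGT", c = "NCGA"))
  expect_equal(segregating_sites(mis, "any_two_nonmissing"), 1)
  expect_equal(segregating_sites(mis, "complete_only"), 1)
  mis2 <- mt_alignment(c(a = "TCGT", b = "ACGT", c = "NCGA"))
  expect_equal(segregating_sites(mis2, "any_two_nonmissing"), 2)
  expect_equal(segregating_sites(mis2, "complete_only"), 1)
})

test_that("Watterson theta matches S/a1 for the published cells", {
  expect_equal(round(watterson_theta(41, 19)$theta_S, 2), 11.73)
  expect_equal(round(watterson_theta(39, 29)$theta_S, 2), 9.93)
  expect_equal(watterson_theta(0, 10)$theta_S, 0)
  w <- watterson_theta(6, 17)
  expect_equal(w$theta_S * w$a1, 6)  # exact identity theta_S = S/a1
})

test_that("Ewens theta inverts the expected haplotype count", {
  expect_equal(round(ewens_theta(17, 3), 2), 0.77)
  expect_equal(round(ewens_theta(27, 3), 2), 0.64)
  expect_equal(round(ewens_theta(29, 8), 2), 3.30)
  expect_equal(ewens_theta(25, 1), 0)
  expect_warning(th <- ewens_theta(5, 5), "unbounded")
  expect_true(is.infinite(th))
  expect_error(ewens_theta(5, 6))

  # plugging the estimate back recovers K; monotone in K at fixed n
  prev <- 0
  for (K in 2:18) {
    th <- ewens_theta(19, K)
    expect_equal(ewens_expected_K(th, 19), K, tolerance = 1e-7)
    expect_gt(th, prev)
    prev <- th
  }
})

test_that("log-space Stirling numbers match the exact integer recurrence", {
  expect_equal(exact_stirling1(6), c(120, 274, 225, 85, 15, 1))
  for (n in c(2, 6, 12, 20)) {
    expect_equal(exp(log_stirling1(n)), exact_stirling1(n), tolerance = 1e-12)
  }
})

test_that("ESF haplotype-number distribution is a proper pmf", {
  for (n in c(2, 5, 10, 20)) {
    for (theta in c(0.3, 1, 5)) {
      p <- esf_K_pmf(theta, n)
      expect_length(p, n)
      expect_true(all(p >= 0))
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_equal(p, exact_esf_pmf(theta, n), tolerance = 1e-10)
    }
  }
})

test_that("Ewens CI bounds solve the equal-tail conditions (n = 6 oracle)", {
  ci <- ewens_theta_ci(6, 3)
  # brute-force tail sums over the full ESF table for n = 6
  expect_equal(sum(exact_esf_pmf(ci["lo"], 6)[3:6]), 0.025, tolerance = 1e-6)
  expect_equal(sum(exact_esf_pmf(ci["hi"], 6)[1:3]), 0.025, tolerance = 1e-6)
  th <- ewens_theta(6, 3)
  expect_lt(ci["lo"], th)
  expect_gt(ci["hi"], th)
  # degenerate left tail at K = 1
  expect_equal(unname(ewens_theta_ci(10, 1)["lo"]), 0)
})

test_that("Ewens CI brackets the point estimate across published cells", {
  for (case in list(c(17, 3), c(27, 3), c(29, 8), c(19, 10))) {
    ci <- ewens_theta_ci(case[1], case[2])
    th <- ewens_theta(case[1], case[2])
    expect_lt(ci["lo"], th)
    expect_gt(ci["hi"], th)
  }
})

test_that("diversity_summary assembles consistent per-group records", {
  sim <- simulate_two_epoch(simulation_config(theta = 3, L = 500, f_max = 0.2,
                                              seed = 123))
  aln <- mt_alignment(rbind(unclass(sim$historical), unclass(sim$modern)),
                      ids = c(rownames(sim$historical), rownames(sim$modern)))
  ds <- suppressWarnings(diversity_summary(aln, groups = sim$groups))
  expect_equal(nrow(ds), 2)
  expect_setequal(ds$group, c("historical", "modern"))
  expect_true(all(ds$Hd >= 0 & ds$Hd <= 1))
  expect_equal(ds$theta_S, ds$S / ds$a1)
  expect_equal(ds$pi, ds$theta_pi / ds$L_eff)
  fin <- is.finite(ds$theta_K)   # K = n leaves the interval undefined
  expect_true(all(ds$theta_K_ci_low[fin] <= ds$theta_K[fin] + 1e-9))
  expect_true(all(ds$theta_K_ci_high[fin] >= ds$theta_K[fin] - 1e-9))
  pol <- attr(ds, "policies")
  expect_identical(pol$deletion, "pairwise")

  # monomorphic group: all estimators collapse to zero
  mono <- mt_alignment(stats::setNames(rep("ACGTACGT", 4), paste0("m", 1:4)))
  dm <- diversity_summary(mono)
  expect_equal(dm$K, 1)
  expect_equal(dm$Hd, 0)
  expect_equal(dm$theta_K, 0)
  expect_equal(dm$theta_S, 0)
  expect_equal(dm$theta_pi, 0)
})

test_that("Hd of large ESF samples approaches theta/(1+theta)", {
  set.seed(2024)
  hd <- replicate(100, {
    counts <- sample_esf_partition(1, 500)
    haplotype_diversity(counts)$Hd
  })
  expect_equal(mean(hd), 0.5, tolerance = 0.05)
})
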