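---
title: "Temporal mitochondrial diversity: models, estimators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal mitochondrial diversity: models, estimators and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitodiv)
```

## The problem

Museum collections make it possible to ask whether a population's genetic
diversity has changed over the last decades or centuries: sequence the same
maternally inherited locus (here, mitochondrial DNA) in historical
specimens and in modern individuals, and compare diversity between the two
epochs. `mitodiv` implements that comparison end to end for aligned
haploid sequences: haplotype inference under explicit missing-data rules,
the classical diversity estimators with their sampling variances, haplotype
rarefaction, a permutation test for between-epoch differences, haplotype
networks, and the conversion of diversity into a female effective
population size.

Two practical features of this kind of data drive most design choices.
First, historical (ancient-DNA-style) sequences carry substantial missing
data — single specimens may be sequenced at well below 1x coverage — so
every estimator must state what it does with `N` sites.  Second, sample
sizes are small (tens of individuals), so small-sample corrections and
exact distributional machinery matter.

## Estimators

Let a group contain $n$ sequences carrying $K$ distinct haplotypes with
counts $c_1,\dots,c_K$ and frequencies $\hat p_i = c_i/n$.

**Haplotype diversity.** The unbiased estimator
$\hat H_d = \frac{n}{n-1}(1 - \sum_i \hat p_i^2)$, with Nei's sampling
variance (implemented in `haplotype_diversity()`).  $\hat H_d$ is the
probability that two randomly drawn sequences carry different haplotypes.

**Theta from pairwise differences.** $\hat\theta_\pi$ is the mean number
of nucleotide differences over all $\binom{n}{2}$ pairs
(`mean_pairwise_differences()`), with Tajima's total variance (which
includes both sampling and evolutionary variance, hence the large SDs
typical of this estimator).  Per-site nucleotide diversity is
$\pi = \hat\theta_\pi / L_\mathrm{eff}$.

**Theta from segregating sites.** Watterson's
$\hat\theta_S = S/a_1$ with $a_1 = \sum_{i=1}^{n-1} 1/i$
(`watterson_theta()`), with the standard estimator variance
$\hat\theta_S/a_1 + a_2 \hat\theta_S^2/a_1^2$.

**Theta from the number of haplotypes.** Under the neutral infinite-alleles
model the haplotype counts follow the Ewens sampling formula, and
$E[K] = \sum_{i=0}^{n-1} \theta/(\theta+i)$ is strictly increasing in
$\theta$.  `ewens_theta()` inverts this expectation by bracketed root
finding (relative tolerance $10^{-10}$); this is also the maximum-likelihood
estimate because $K$ is sufficient for $\theta$ under the ESF.
`ewens_theta_ci()` inverts the exact sampling distribution
$P(K=k\mid\theta,n) = |s(n,k)|\,\theta^k / \theta^{(n)}$ — with unsigned
Stirling numbers of the first kind computed in log space
(`log_stirling1()`), so sample sizes in the hundreds are safe — as an
equal-tail interval: the bounds solve
$P(K \ge k_{obs}) = P(K \le k_{obs}) = (1-\text{level})/2$.  Equal-tail is
a deliberate choice; the interval convention behind published Arlequin-style
brackets is undocumented, and the package asserts only distributional
properties of its own intervals (they bracket the MLE; at $n=6$ they agree
with brute-force tail sums over the full Stirling table).

Degenerate cases are explicit: $K=1$ gives $\hat\theta_K = 0$ and a
left-degenerate interval; $K=n$ has no finite MLE (it is the
$\theta\to\infty$ limit) and returns `Inf` flagged `unbounded` rather than
a spuriously large number.

## Missing data policies

Gaps (`-`) are treated as missing and stored as `N` throughout: in
intraspecific mitochondrial work the indel-rich, hard-to-align segments are
excluded from the alignment rather than modelled, so a residual gap carries
no usable state.  On top of that convention, each operation exposes its
policy:

* **Haplotype collapsing** (`collapse_haplotypes()`): `strict` treats
  sequences as distinct unless identical site-by-site (`N` matches only
  `N`); `merge_compatible` merges sequences that agree at all mutually
  observed sites, building a consensus representative.  Merging is
  order-dependent when one sequence is compatible with two mutually
  incompatible haplotypes; the first-seen haplotype wins, a deterministic
  tie-break recorded in the documentation.  Neither policy claims to
  replicate any particular legacy software's internal counting — published
  haplotype counts under heavy missing data are software-specific (the
  package's own acceptance checks document one such discrepancy, a printed
  per-sequence theta consistent only with one-more-haplotype than the
  printed count).
* **Distances**: `pairwise` deletion (default) compares each pair at sites
  observed in both; `complete` deletion uses only sites observed in all
  sequences.  Pairwise is the default because historical sequences at very
  low coverage would otherwise collapse the usable length toward zero.
* **Segregating sites**: `any_two_nonmissing` (default) counts a site once
  two distinct observed states exist; `complete_only` restricts to fully
  observed columns.
* **Per-site scaling**: $L_\mathrm{eff}$ defaults to the mean number of
  mutually observed sites per pair, consistent with pairwise deletion; a
  fixed length can be supplied instead (and is what reproduces published
  values computed on complete modern data).

Default completeness threshold for filtering short-fragment data
(`filter_by_completeness()`): 0.5 missing fraction — exclusions in the
motivating use case are stated without a numeric threshold, and 0.5 marks
the point where a 425-bp fragment no longer carries most of its sites.

## Rarefaction

`haplotype_accumulation()` permutes individuals (without replacement — the
classic accumulation design) and averages the cumulative haplotype count;
`expected_accumulation_exact()` provides the closed-form hypergeometric
expectation $E[K_g] = \sum_h [1 - \binom{n-c_h}{g}/\binom{n}{g}]$ as an
independent oracle.  The reported `se_K` is the standard deviation across
permutations (the plotted ribbon), not the Monte-Carlo error of the mean.

## Permutation test

`diversity_difference_test()` uses the two-sided statistic
$|\Delta| = |\mathrm{stat}_1 - \mathrm{stat}_2|$, pooling individuals and
redrawing groups of the observed sizes.  Monte-Carlo p-values carry the
$+1/(B+1)$ correction so $p = 0$ is impossible; when
$\binom{n_1+n_2}{n_1} \le 10^5$ all splits are enumerated and the exact
proportion is reported instead.  For the $\pi$ statistic all pairwise
distances are computed once and permutations only shuffle indices.  The
test's size is checked by simulation: drawing both groups from one Ewens
population ($\theta = 2$, $n = 20$ per group, 500 replicates) must give a
rejection rate in $[0.03, 0.08]$ at nominal $0.05$.

## Haplotype networks

`minimum_spanning_network()` runs Kruskal with equal-weight closure, so the
result is the union of all minimum spanning trees.
`median_joining()` (relaxation $\varepsilon$ fixed at 0, the standard
default) iteratively proposes, for every triplet of current nodes, the
site-wise majority-vote median sequence, and accepts the median that most
reduces total minimum-spanning-tree cost, stopping at a fixpoint; median
nodes of degree < 3 are deleted as obsolete.  Ties in the majority vote
(three distinct states at a site) resolve to the first node of the triplet
in input order — deterministic by construction.  The majority vote acts
directly on nucleotide states; for the three-state ties this is equivalent
to the binary-indicator expansion used in classic formulations, with the
same tie-break.  Convergence is guarded at $10K$ iterations.  On the
canonical `AAG / AGA / GAA` triple the algorithm adds the `AAA` median,
dropping the network cost from 4 to 3.

## The synthetic-data generator

Because raw sequence data cannot ship with the package, every stage is
exercised against generated data whose statistical structure matches the
analysis assumptions:

* `sample_esf_partition()` — Hoppe-urn draws from the Ewens sampling
  formula (the model behind $\hat\theta_K$); validated by an exact
  chi-square goodness-of-fit against the Stirling-number probabilities at
  small $n$.
* `coalescent_infinite_sites()` — Kingman coalescent with Poisson
  mutations, each at a fresh site; validated against
  $E[S] = \theta a_1$ and $E[\hat\theta_\pi] = \theta$ over thousands of
  replicates.
* `mask_missing()` — per-individual uniform site masking emulating
  low-coverage museum specimens.
* `simulate_two_epoch()` — one coalescent haplotype pool, a historical
  sample, Wright-Fisher multinomial drift of the pool frequencies, then a
  modern sample.  The drift phase adds no new mutations: the decades
  separating the epochs are negligible relative to the mitochondrial
  mutational timescale.  This is a test harness, not a fitted demographic
  model — it emulates drift-driven haplotype loss, not any particular
  bottleneck history.

Default study conditions, chosen once to match the whole-mitogenome regime
of the motivating system: $\theta = 11.7$ (so $E[S] \approx 41$ at
$n = 19$), $n = 19$ historical / 29 modern, $L = 15{,}460$ bp, historical
missing fractions uniform on $[0, 0.3]$, drift at $N_e = 350$ females
(about the current number of breeding females, one per pack) for $G = 15$
generations (roughly five decades at a three-year generation time).
Calibration tests run at reduced scale — e.g. $n = 10$, $\theta = 5$,
$L = 500$ for the coalescent moment checks, and $L = 300$ with
$N_e = 50$, $G = 120$ generations for the drift-decline property — sizes
chosen so each property is measured with thousands of replicates in
seconds.

What the generator does *not* emulate: heterochronous (serial-sample)
coalescence between the epochs, post-mortem damage substitutions
(C-to-T deamination), NUMT contamination, selection, recombination or
migration.  Passing tests therefore demonstrate correctness of the
estimators and machinery under the neutral model with missing data — not
robustness to aDNA damage artefacts, which must be handled upstream.

## Effective population size

For a haploid maternally inherited locus, $\theta = 2 N_{ef} \mu$ per
site, so `female_effective_size()` reports
$N_{ef} = (\theta/L) / (2\mu)$ at both ends of a mutation-rate interval.
The motivating calculation uses a wolf mitogenome rate with 95% posterior
density $1.85$–$3.0 \times 10^{-7}$ substitutions/site/generation (the
source prints the interval with the exponent sign dropped; only the
negative-exponent reading yields plausible sizes, and the package treats it
as such).  Unrounded theta estimates should be piped in: the
haplotype-based estimate for the modern mitogenome data is
$\hat\theta_K(n{=}29, K{=}8) = 3.2989$, and rounding it first shifts the
resulting $N_{ef}$ visibly.

## Numerical choices

* Ewens root finding brackets $[10^{-10}, 10^6]$, expanding upward
  tenfold as needed; relative tolerance $10^{-10}$.
* Stirling numbers in log space via
  $|s(n,k)| = |s(n-1,k-1)| + (n-1)|s(n-1,k)|$ with log-sum-exp; exact to
  $10^{-12}$ relative against integer arithmetic through $n = 20$.
* Binomial coefficients in the rarefaction expectation via `lchoose`, so
  $\binom{a}{b} = 0$ for $a < b$ falls out as $\exp(-\infty)$.
* Report rounding follows the conventions of published tables: 3 decimals
  for $H_d$, 2 for per-sequence $\theta$, 2 significant figures for
  per-site $\pi$.
* One master seed fans out to per-stage child seeds via
  `child_seed(seed, k)` (affine map modulo $2^{31}-1$), so each simulation
  stage is independently reproducible.

## Known limitations

* The merge-compatible collapsing is greedy in input order; a globally
  optimal (minimum-K) merge is NP-hard and not attempted.
* Equal-tail ESF intervals need not match legacy software's printed
  brackets (convention undocumented there).
* The median-joining search enumerates all node triplets; fine for the
  tens of haplotypes typical of intraspecific mitochondrial data, not for
  hundreds.
* Rarefaction interpolates only; no Chao-type extrapolation beyond the
  observed sample size.

## A worked run

```{r example}
sim <- simulate_two_epoch(simulation_config(theta = 5, n_hist = 12,
                                            n_modern = 16, L = 2000,
                                            f_max = 0.2, seed = 7))
aln <- mt_alignment(rbind(unclass(sim$historical), unclass(sim$modern)),
                    ids = c(rownames(sim$historical), rownames(sim$modern)))
diversity_summary(aln, groups = sim$groups)
```
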