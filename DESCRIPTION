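Package: mitodiv
Title: Temporal Mitochondrial Haplotype Diversity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing mitochondrial DNA diversity between two
    sampling epochs (e.g. museum specimens versus modern individuals).
    Reads aligned haploid sequences, collapses them into haplotypes under
    explicit missing-data policies, and computes classical population
    genetic diversity estimators: haplotype diversity (Hd) with its
    sampling variance, nucleotide diversity (pi), Watterson's theta from
    segregating sites, theta from mean pairwise differences with Tajima's
    variance, and the Ewens estimator of theta from the number of
    haplotypes with exact confidence intervals based on the Ewens sampling
    formula and unsigned Stirling numbers of the first kind. Also provides
    haplotype accumulation (rarefaction) curves with a closed-form
    expectation, permutation tests for between-epoch differences in
    diversity, minimum-spanning and median-joining haplotype networks, and
    conversion of theta into female effective population size under a
    mutation-rate interval. A synthetic-data module generates Ewens
    partitions, infinite-sites coalescent alignments, ancient-DNA-style
    missing-data masks, and two-epoch drift scenarios so the whole
    pipeline can be exercised without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
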