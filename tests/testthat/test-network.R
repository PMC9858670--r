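test_that("hamming distances match a brute-force site loop", {
  haps <- matrix(c("A", "C", "G", "T",
                   "A", "C", "G", "T",
                   "A", "C", "C", "A"), nrow = 3, byrow = TRUE,
                 dimnames = list(c("H1", "H2", "H3"), NULL))
  d <- hamming_matrix(haps)
  expect_equal(d["H1", "H2"], 0)
  expect_equal(d["H1", "H3"], 2)
  expect_equal(unname(diag(d)), c(0, 0, 0))

  set.seed(17)
  mat <- unclass(random_alignment(5, 20))
  rownames(mat) <- paste0("H", 1:5)
  d <- hamming_matrix(mat)
  for (i in 1:4) {
    for (j in (i + 1):5) {
      brute <- sum(vapply(seq_len(20),
                          function(s) mat[i, s] != mat[j, s], logical(1)))
      expect_equal(d[i, j], brute)
      expect_equal(d[j, i], brute)
    }
  }
})

test_that("sites missing in any haplotype are excluded before distances", {
  haps <- matrix(c("A", "N", "G",
                   "A", "C", "T"), nrow = 2, byrow = TRUE,
                 dimnames = list(c("H1", "H2"), NULL))
  d <- hamming_matrix(haps)
  expect_equal(d["H1", "H2"], 1)  # only sites 1 and 3 compared
  allN <- matrix(c("N", "A"), nrow = 2,
                 dimnames = list(c("H1", "H2"), NULL))
  expect_error(hamming_matrix(allN), "non-missing")
})

test_that("minimum spanning network keeps unique MSTs and closes ties", {
  # chain: unique MST
  d <- matrix(c(0, 1, 2,
                1, 0, 1,
                2, 1, 0), 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  net <- minimum_spanning_network(d)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(paste(net$edges$node1, net$edges$node2),
                  c("A B", "B C"))

  # equilateral triple: all three edges enter the network
  d3 <- matrix(2, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(d3) <- 0
  net3 <- minimum_spanning_network(d3)
  expect_equal(nrow(net3$edges), 3)

  # two haplotypes: single edge carrying the mutation count
  d2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  net2 <- minimum_spanning_network(d2)
  expect_equal(net2$edges$weight, 1)
})

test_that("median joining adds the majority-consensus intermediate", {
  haps <- matrix(c("A", "A", "G",
                   "A", "G", "A",
                   "G", "A", "A"), nrow = 3, byrow = TRUE,
                 dimnames = list(c("H1", "H2", "H3"), NULL))
  net <- median_joining(haps)
  med <- net$nodes$id[net$nodes$kind == "median"]
  expect_length(med, 1)
  expect_equal(nrow(net$edges), 3)
  expect_true(all(net$edges$weight == 1))
  expect_true(all(med %in% c(net$edges$node1, net$edges$node2)))
  expect_equal(sum(net$edges$weight), 3)  # beats the 4-step spanning tree
})

test_that("two haplotypes never gain a median", {
  haps <- matrix(c("A", "A", "A", "G",
                   "A", "C", "A", "G"), nrow = 2, byrow = TRUE,
                 dimnames = list(c("H1", "H2"), NULL))
  net <- median_joining(haps)
  expect_equal(sum(net$nodes$kind == "median"), 0)
  expect_equal(nrow(net$edges), 1)
})

test_that("networks stay connected and respect the Hamming lower bound", {
  set.seed(23)
  for (rep in 1:5) {
    n <- sample(4:8, 1)
    aln <- random_alignment(n, sample(10:30, 1))
    ht <- collapse_haplotypes(aln)
    net <- median_joining(ht)
    g <- as_igraph(net)
    expect_true(igraph::is_connected(g))
    d <- hamming_matrix(ht)
    ids <- rownames(d)
    for (i in seq_along(ids)[-1]) {
      pl <- net_path_length(net, ids[1], ids[i])
      expect_gte(pl + 1e-9, d[ids[1], ids[i]])
    }
    # the final edge set is exactly the equal-weight-closed MSN on its nodes
    expect_true(all(net$edges$weight >= 1))
  }
})

test_that("median counts are zero and sampled counts carry the groups", {
  aln <- mt_alignment(c(a = "AAG", b = "AGA", c = "GAA", d = "AAG"))
  ht <- collapse_haplotypes(aln, groups = c(a = "historical", b = "historical",
                                            c = "modern", d = "modern"))
  net <- median_joining(ht)
  expect_equal(sum(net$counts), 4)
  med <- net$nodes$id[net$nodes$kind == "median"]
  if (length(med)) expect_true(all(rowSums(net$counts[med, , drop = FALSE]) == 0))
})

test_that("network exports write GraphML and TSV edge lists", {
  haps <- matrix(c("A", "A", "G",
                   "A", "G", "A",
                   "G", "A", "A"), nrow = 3, byrow = TRUE,
                 dimnames = list(c("H1", "H2", "H3"), NULL))
  net <- median_joining(haps)
  gml <- withr::local_tempfile(fileext = ".graphml")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_graphml(net, gml)
  expect_true(file.size(gml) > 0)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(back), nrow(net$nodes))
  expect_equal(igraph::gsize(back), nrow(net$edges))
  write_edges_tsv(net, tsv)
  edges <- read.delim(tsv)
  expect_named(edges, c("node1", "node2", "mutations"))
  expect_equal(nrow(edges), 3)
})
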