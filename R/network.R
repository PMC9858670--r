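#' Hamming distance matrix between haplotypes
#'
#' Pairwise counts of differing sites between representative haplotype
#' sequences.  Network construction needs completely observed characters,
#' so the comparison is restricted to the sites that are non-missing in
#' every haplotype; an error is raised when no such site remains.
#'
#' @param haps a `haplotype_table` from [collapse_haplotypes()], or a
#'   character matrix of haplotype sequences (rows named by haplotype id).
#' @return a symmetric integer matrix of mutation counts.
#' @export
hamming_matrix <- function(haps) {
  mat <- if (inherits(haps, "haplotype_table")) haps$haplotypes else haps
  keep <- colSums(mat == "N") == 0L
  if (!any(keep)) stop("no site is non-missing in all haplotypes")
  mat <- mat[, keep, drop = FALSE]
  m <- nrow(mat)
  d <- matrix(0L, m, m, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      d[i, j] <- d[j, i] <- sum(mat[i, ] != mat[j, ])
    }
  }
  d
}

# total weight of a minimum spanning tree (Prim), for the MJN cost criterion
.mst_cost <- function(d) {
  m <- nrow(d)
  if (m <= 1L) return(0)
  in_tree <- c(TRUE, rep(FALSE, m - 1L))
  best <- d[1L, ]
  total <- 0
  for (step in seq_len(m - 1L)) {
    cand <- which(!in_tree)
    nxt <- cand[which.min(best[cand])]
    total <- total + best[nxt]
    in_tree[nxt] <- TRUE
    best <- pmin(best, d[nxt, ])
  }
  total
}

# union-find component labels helper
.find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Minimum spanning network
#'
#' The union of all minimum spanning trees on a haplotype distance matrix:
#' Kruskal's algorithm with equal-weight closure — when components are
#' joined at distance d, every inter-component pair at distance d
#' (evaluated against the components as they stood before that distance
#' level) contributes an edge.  Edges are emitted in (weight, id, id)
#' lexicographic order so output is byte-stable.
#'
#' @param d symmetric distance matrix with haplotype ids as dimnames
#'   (e.g. from [hamming_matrix()]).
#' @param counts optional per-group count matrix (haplotypes x groups) used
#'   to annotate nodes, e.g. the `counts` element of a `haplotype_table`.
#' @return an object of class `haplotype_network`: list with `nodes`
#'   (data frame: id, kind), `counts`, `edges` (data frame: node1, node2,
#'   weight) and `epsilon`.
#' @export
minimum_spanning_network <- function(d, counts = NULL) {
  ids <- rownames(d)
  m <- length(ids)
  edges <- data.frame(node1 = character(0), node2 = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  if (m > 1L) {
    parent <- seq_len(m)
    ij <- which(upper.tri(d), arr.ind = TRUE)
    w <- d[ij]
    ord <- order(w, ids[ij[, 1L]], ids[ij[, 2L]])
    ij <- ij[ord, , drop = FALSE]; w <- w[ord]
    for (lvl in unique(w)) {
      at <- which(w == lvl)
      comp_before <- vapply(seq_len(m), function(i) .find(parent, i), integer(1))
      added <- ij[at, , drop = FALSE][
        comp_before[ij[at, 1L]] != comp_before[ij[at, 2L]], , drop = FALSE]
      if (nrow(added)) {
        edges <- rbind(edges, data.frame(node1 = ids[added[, 1L]],
                                         node2 = ids[added[, 2L]],
                                         weight = lvl,
                                         stringsAsFactors = FALSE))
        for (r in seq_len(nrow(added)))
          parent[.find(parent, added[r, 1L])] <- .find(parent, added[r, 2L])
      }
    }
  }
  kind <- ifelse(grepl("^median", ids), "median", "sampled")
  if (is.null(counts)) {
    counts <- matrix(0L, m, 1L, dimnames = list(ids, "all"))
    counts[kind == "sampled", 1L] <- 1L
  } else {
    full <- matrix(0L, m, ncol(counts), dimnames = list(ids, colnames(counts)))
    shared <- intersect(ids, rownames(counts))
    full[shared, ] <- counts[shared, , drop = FALSE]
    counts <- full
  }
  structure(list(nodes = data.frame(id = ids, kind = kind,
                                    stringsAsFactors = FALSE),
                 counts = counts, edges = edges, epsilon = 0),
            class = "haplotype_network")
}

#' Median-joining haplotype network
#'
#' Builds a median-joining network with relaxation parameter epsilon fixed
#' at 0.  The algorithm iterates: construct the minimum spanning network on
#' the current node set; for every triplet of nodes compute the site-wise
#' majority-vote median sequence (a candidate unsampled intermediate); add
#' the median giving the largest reduction in total minimum-spanning-tree
#' cost, if any reduces it; repeat to a fixpoint.  Median nodes that end up
#' with degree < 3 in the final network are obsolete and deleted.  At a
#' site where all three triplet states differ the vote is tied and resolves
#' to the state of the first node of the triplet in input order, so results
#' are deterministic.
#'
#' @param haps a `haplotype_table` or character matrix of haplotype
#'   sequences (as for [hamming_matrix()]).
#' @param max_iter safety cap on median-addition rounds; default 10 times
#'   the number of haplotypes.
#' @return a `haplotype_network` whose median nodes are named
#'   `median1, median2, ...` and carry zero sample counts.
#' @examples
#' haps <- matrix(c("A","A","G",  "A","G","A",  "G","A","A"),
#'                nrow = 3, byrow = TRUE,
#'                dimnames = list(c("H1","H2","H3"), NULL))
#' net <- median_joining(haps)   # adds the AAA median
#' net$edges
#' @export
median_joining <- function(haps, max_iter = NULL) {
  counts <- if (inherits(haps, "haplotype_table")) haps$counts else NULL
  mat <- if (inherits(haps, "haplotype_table")) haps$haplotypes else haps
  keep <- colSums(mat == "N") == 0L
  if (!any(keep)) stop("no site is non-missing in all haplotypes")
  mat <- mat[, keep, drop = FALSE]
  K <- nrow(mat)
  if (is.null(max_iter)) max_iter <- 10L * K
  n_med <- 0L

  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter)
      stop("median-joining did not converge within ", max_iter,
           " iterations (", K, " haplotypes)")
    m <- nrow(mat)
    if (m < 3L) break
    d <- .hamming_complete(mat)
    cost <- .mst_cost(d)
    best_red <- 0
    best_med <- NULL
    existing <- apply(mat, 1L, paste, collapse = "")
    for (i in seq_len(m - 2L)) {
      for (j in (i + 1L):(m - 1L)) {
        for (k in (j + 1L):m) {
          med <- .majority_median(mat[i, ], mat[j, ], mat[k, ])
          key <- paste(med, collapse = "")
          if (key %in% existing) next
          dm <- .row_dist(mat, med)
          d2 <- rbind(cbind(d, dm), c(dm, 0))
          red <- cost - .mst_cost(d2)
          if (red > best_red + 1e-9 ||
              (red > 0 && abs(red - best_red) <= 1e-9 &&
               (is.null(best_med) || key < paste(best_med, collapse = "")))) {
            best_red <- red
            best_med <- med
          }
        }
      }
    }
    if (is.null(best_med)) break
    n_med <- n_med + 1L
    mat <- rbind(mat, best_med)
    rownames(mat)[nrow(mat)] <- paste0("median", n_med)
  }

  # prune obsolete medians (degree < 3) until stable
  repeat {
    net <- minimum_spanning_network(.hamming_complete(mat), counts = counts)
    deg <- table(factor(c(net$edges$node1, net$edges$node2),
                        levels = net$nodes$id))
    drop <- net$nodes$id[net$nodes$kind == "median" & deg < 3L]
    if (!length(drop)) break
    mat <- mat[setdiff(rownames(mat), drop), , drop = FALSE]
  }
  net
}

# hamming matrix for a complete (no-N) character matrix
.hamming_complete <- function(mat) {
  m <- nrow(mat)
  d <- matrix(0L, m, m, dimnames = list(rownames(mat), rownames(mat)))
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) d[i, j] <- d[j, i] <- sum(mat[i, ] != mat[j, ])
    }
  }
  d
}

.row_dist <- function(mat, vec) {
  apply(mat, 1L, function(r) sum(r != vec))
}

# site-wise majority vote of three sequences; full three-way ties resolve
# to the first sequence's state
.majority_median <- function(a, b, c) {
  med <- a
  bc <- b == c
  med[bc] <- b[bc]   # b and c agree (covers a==b==c and b==c != a)
  med
}

#' Convert a haplotype network to an igraph graph
#'
#' Vertices carry `kind` and one `count_<group>` attribute per group;
#' edges carry `mutations`.
#'
#' @param net a `haplotype_network`.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$edges$node1, to = net$edges$node2,
               mutations = net$edges$weight),
    directed = FALSE,
    vertices = net$nodes)
  for (grp in colnames(net$counts)) {
    g <- igraph::set_vertex_attr(g, paste0("count_", grp),
                                 value = net$counts[net$nodes$id, grp])
  }
  g
}

#' Write a haplotype network to GraphML or a TSV edge list
#'
#' @param net a `haplotype_network`.
#' @param path output path.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_edges_tsv <- function(net, path) {
  utils::write.table(
    data.frame(node1 = net$edges$node1, node2 = net$edges$node2,
               mutations = net$edges$weight),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("haplotype_network: %d sampled + %d median nodes, %d edges (epsilon = %g)\n",
              sum(x$nodes$kind == "sampled"), sum(x$nodes$kind == "median"),
              nrow(x$edges), x$epsilon))
  invisible(x)
}

#' @export
plot.haplotype_network <- function(x, ...) {
  g <- as_igraph(x)
  tot <- rowSums(x$counts)[x$nodes$id]
  sampled <- x$nodes$kind == "sampled"
  size <- ifelse(sampled, 8 + 4 * sqrt(tot), 2)
  igraph::plot.igraph(
    g, vertex.size = size,
    vertex.color = ifelse(sampled, "steelblue", "black"),
    vertex.label = ifelse(sampled, x$nodes$id, NA),
    edge.label = x$edges$weight, ...)
  invisible(x)
}
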