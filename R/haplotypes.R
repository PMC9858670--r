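#' Collapse aligned sequences into haplotypes
#'
#' Two missing-data policies are available.  Under `"strict"`, two sequences
#' share a haplotype only when they are identical at every site, with N
#' matching only N.  Under `"merge_compatible"`, sequences that agree at all
#' mutually non-missing sites are merged into one haplotype whose
#' representative sequence is the site-wise consensus (missing sites filled
#' in from whichever member observed them).  A sequence compatible with
#' several mutually incompatible haplotypes is assigned to the first-seen
#' compatible haplotype in input order; this tie-break is deterministic and
#' recorded here so results are reproducible.
#'
#' Haplotypes are labelled `H1, H2, ...` in order of first appearance.
#'
#' @param aln an [mt_alignment()].
#' @param groups optional group assignment: a data frame with columns
#'   `id`/`group` (see [read_groups()]) or a named character vector.  When
#'   omitted all individuals form a single group `"all"`.
#' @param missing_policy `"strict"` or `"merge_compatible"`.
#' @return an object of class `haplotype_table`: a list with
#'   \describe{
#'     \item{haplotypes}{character matrix of representative sequences, one
#'       row per haplotype}
#'     \item{assignment}{named character vector, individual id -> haplotype id}
#'     \item{counts}{integer matrix, haplotypes x groups}
#'     \item{K}{number of distinct haplotypes}
#'     \item{missing_policy}{the policy used}
#'   }
#' @examples
#' aln <- mt_alignment(c(a = "ACGT", b = "ACGT", c = "ACCT"))
#' ht <- collapse_haplotypes(aln)
#' ht$K            # 2
#' haplotype_counts(ht)
#' @export
collapse_haplotypes <- function(aln, groups = NULL,
                                missing_policy = c("strict", "merge_compatible")) {
  missing_policy <- match.arg(missing_policy)
  if (nrow(aln) == 0L) stop("empty alignment")
  ids <- rownames(aln)
  mat <- unclass(aln)

  reps <- list()           # representative sequences (character vectors)
  members <- list()        # integer indices of member sequences
  assignment <- character(nrow(mat))

  for (i in seq_len(nrow(mat))) {
    s <- mat[i, ]
    hit <- 0L
    for (h in seq_along(reps)) {
      r <- reps[[h]]
      if (missing_policy == "strict") {
        if (all(r == s)) { hit <- h; break }
      } else {
        both <- r != "N" & s != "N"
        if (!any(r[both] != s[both])) { hit <- h; break }
      }
    }
    if (hit == 0L) {
      reps[[length(reps) + 1L]] <- s
      members[[length(members) + 1L]] <- i
      hit <- length(reps)
    } else {
      members[[hit]] <- c(members[[hit]], i)
      if (missing_policy == "merge_compatible") {
        fill <- reps[[hit]] == "N" & s != "N"
        reps[[hit]][fill] <- s[fill]
      }
    }
    assignment[i] <- paste0("H", hit)
  }

  names(assignment) <- ids
  hap_ids <- paste0("H", seq_along(reps))
  rep_mat <- do.call(rbind, reps)
  rownames(rep_mat) <- hap_ids

  grp <- if (is.null(groups)) {
    stats::setNames(rep("all", length(ids)), ids)
  } else {
    .group_vector(groups, ids)
  }
  counts <- table(factor(assignment, levels = hap_ids),
                  factor(grp, levels = unique(grp)))
  counts <- unclass(counts)
  storage.mode(counts) <- "integer"

  structure(list(haplotypes = rep_mat, assignment = assignment,
                 counts = counts, K = length(reps),
                 missing_policy = missing_policy),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("haplotype_table: %d haplotypes, %d individuals, policy = %s\n",
              x$K, length(x$assignment), x$missing_policy))
  print(x$counts)
  invisible(x)
}

#' Haplotype counts for a group
#'
#' @param ht a `haplotype_table` from [collapse_haplotypes()].
#' @param group group label; default the first group.
#' @return integer vector of per-haplotype counts (zero counts dropped).
#' @export
haplotype_counts <- function(ht, group = colnames(ht$counts)[1L]) {
  cc <- ht$counts[, group]
  as.integer(cc[cc > 0])
}

#' Write haplotype tables as TSV
#'
#' `write_haplotype_counts()` writes `haplotype<TAB>group<TAB>count` rows;
#' `write_haplotype_assignment()` writes `id<TAB>haplotype` rows.
#'
#' @param ht a `haplotype_table`.
#' @param path output path.
#' @export
write_haplotype_counts <- function(ht, path) {
  long <- expand.grid(haplotype = rownames(ht$counts),
                      group = colnames(ht$counts),
                      stringsAsFactors = FALSE)
  long$count <- ht$counts[cbind(long$haplotype, long$group)]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_haplotype_counts
#' @export
write_haplotype_assignment <- function(ht, path) {
  utils::write.table(data.frame(id = names(ht$assignment),
                                haplotype = unname(ht$assignment)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
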