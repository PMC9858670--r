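#' Aligned haploid sequences
#'
#' An `mt_alignment` is a character matrix with one row per sequence and one
#' column per alignment site, over the alphabet A, C, G, T, N.  Alignment
#' gaps (`-`) are treated as missing data and stored as `N`: for
#' intraspecific mitochondrial alignments the hard-to-align indel-rich
#' regions are excluded upstream rather than modelled, so a gap carries no
#' more information than an uncalled base.
#'
#' @param seqs character vector of equal-length sequence strings, or a
#'   character matrix with one row per sequence.
#' @param ids sequence identifiers; must be unique.  Defaults to names or
#'   row names of `seqs`.
#' @param alphabet_policy what to do with IUPAC ambiguity codes or other
#'   characters outside A/C/G/T/N/-: `"strict"` raises an error,
#'   `"map_to_N"` converts them to N.
#' @return an object of class `mt_alignment`: a character matrix with
#'   row names set to the sequence ids.
#' @examples
#' aln <- mt_alignment(c(a = "ACGT", b = "ACGA"))
#' n_seq(aln)
#' aln_length(aln)
#' @export
mt_alignment <- function(seqs, ids = NULL,
                         alphabet_policy = c("strict", "map_to_N")) {
  alphabet_policy <- match.arg(alphabet_policy)
  if (is.matrix(seqs)) {
    mat <- seqs
    if (is.null(ids)) ids <- rownames(mat)
  } else {
    if (is.null(ids)) ids <- names(seqs)
    if (length(seqs) == 0L) stop("alignment has no sequences")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      bad <- which(lens != lens[1L])[1L]
      stop(sprintf("ragged alignment: sequence '%s' has length %d, expected %d",
                   if (is.null(ids)) as.character(bad) else ids[bad],
                   lens[bad], lens[1L]))
    }
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  }
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(mat)))
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
  if (ncol(mat) == 0L) stop("alignment length must be positive")
  mat <- toupper(mat)
  mat[mat == "-"] <- "N"
  bad <- !(mat %in% c("A", "C", "G", "T", "N"))
  if (any(bad)) {
    if (alphabet_policy == "strict") {
      idx <- which(bad)[1L] - 1L
      stop(sprintf(
        "non-alphabet character '%s' in sequence '%s' at site %d (use alphabet_policy = \"map_to_N\" to mask)",
        mat[which(bad)[1L]], ids[idx %% nrow(mat) + 1L], idx %/% nrow(mat) + 1L))
    }
    mat[bad] <- "N"
  }
  dimnames(mat) <- list(ids, NULL)
  class(mat) <- c("mt_alignment", "matrix")
  mat
}

#' @rdname mt_alignment
#' @param x an `mt_alignment`.
#' @export
n_seq <- function(x) nrow(x)

#' @rdname mt_alignment
#' @export
aln_length <- function(x) ncol(x)

#' @export
print.mt_alignment <- function(x, ...) {
  cat(sprintf("mt_alignment: %d sequences, %d sites (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(x == "N")))
  invisible(x)
}

#' @export
`[.mt_alignment` <- function(x, i, j, ...) {
  out <- unclass(x)[i, j, drop = FALSE]
  class(out) <- c("mt_alignment", "matrix")
  out
}

#' Read a FASTA alignment
#'
#' Reads an aligned FASTA file (wrapped or single-line) into an
#' [mt_alignment()].  Lowercase is normalised to uppercase and gaps become N
#' (see [mt_alignment()] for the missing-data convention).
#'
#' @param path path to a FASTA file.
#' @inheritParams mt_alignment
#' @return an `mt_alignment`.
#' @export
read_fasta_alignment <- function(path, alphabet_policy = c("strict", "map_to_N")) {
  alphabet_policy <- match.arg(alphabet_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  dna <- suppressWarnings(ape::read.FASTA(path))
  if (length(dna) == 0L) stop("no FASTA records in ", path)
  chars <- lapply(as.character(dna), function(s) toupper(s))
  lens <- lengths(chars)
  if (length(unique(lens)) > 1L) {
    bad <- which(lens != lens[1L])[1L]
    stop(sprintf("ragged alignment: sequence '%s' has length %d, expected %d",
                 names(dna)[bad], lens[bad], lens[1L]))
  }
  mt_alignment(do.call(rbind, chars), ids = names(dna),
               alphabet_policy = alphabet_policy)
}

#' Write a FASTA alignment
#'
#' Writes sequences wrapped at 60 columns.
#'
#' @param aln an [mt_alignment()].
#' @param path output path.
#' @export
write_fasta_alignment <- function(aln, path) {
  dna <- ape::as.DNAbin(unclass(aln))
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' Read and write group assignments
#'
#' Group files are tab-separated with a header line
#' `id<TAB>group[<TAB>year][<TAB>locality]`.  Every sequence id must appear
#' in exactly one group.
#'
#' @param path path to a TSV file.
#' @return a data frame with columns `id`, `group` and any optional columns.
#' @export
read_groups <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("id", "group") %in% names(g)))
    stop("groups file must have columns 'id' and 'group'")
  if (anyDuplicated(g$id))
    stop("duplicate id in groups file: ", g$id[duplicated(g$id)][1L])
  g
}

#' @rdname read_groups
#' @param groups a data frame as returned by [read_groups()].
#' @export
write_groups <- function(groups, path) {
  utils::write.table(groups, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# named vector id -> group from either a data.frame or a named vector
.group_vector <- function(groups, ids) {
  if (is.data.frame(groups)) {
    v <- stats::setNames(groups$group, groups$id)
  } else {
    v <- groups
  }
  missing <- setdiff(ids, names(v))
  if (length(missing))
    stop("no group assignment for id(s): ", paste(missing, collapse = ", "))
  v[ids]
}

#' Per-sequence completeness and completeness filtering
#'
#' `completeness()` returns the fraction of non-missing sites per sequence.
#' `filter_by_completeness()` drops sequences whose missing fraction exceeds
#' a threshold, mirroring the common practice of excluding low-coverage
#' museum specimens from short-fragment analyses.
#'
#' @param aln an [mt_alignment()].
#' @param max_missing_fraction maximum tolerated fraction of missing (N)
#'   sites, in `[0, 1]`.  The retained alignment is returned with an
#'   attribute `excluded_ids` listing dropped sequences.
#' @export
completeness <- function(aln) {
  1 - rowMeans(unclass(aln) == "N")
}

#' @rdname completeness
#' @export
filter_by_completeness <- function(aln, max_missing_fraction = 0.5) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1)
  miss <- rowMeans(unclass(aln) == "N")
  keep <- miss <= max_missing_fraction
  if (!any(keep))
    stop("all sequences exceed the missing-data threshold")
  excluded <- rownames(aln)[!keep]
  if (length(excluded))
    message("excluding ", length(excluded), " sequence(s): ",
            paste(excluded, collapse = ", "))
  out <- aln[keep, ]
  attr(out, "excluded_ids") <- excluded
  out
}

#' Site counts usable after missing-data deletion
#'
#' With `deletion = "complete"`, the number of sites with no missing data in
#' any sequence (a single integer).  With `deletion = "pairwise"`, an
#' n-by-n matrix giving, for each pair of sequences, the number of sites
#' non-missing in both.
#'
#' @param aln an [mt_alignment()].
#' @param deletion `"complete"` or `"pairwise"`.
#' @export
effective_length <- function(aln, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  ok <- unclass(aln) != "N"
  if (deletion == "complete") {
    sum(colSums(!ok) == 0L)
  } else {
    m <- ok %*% t(ok)
    storage.mode(m) <- "integer"
    dimnames(m) <- list(rownames(aln), rownames(aln))
    m
  }
}
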