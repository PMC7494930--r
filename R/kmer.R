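# Canonical k-mer presence/absence profiling and binary (Jaccard) distances —
# the alignment-free whole-genome diversity computation.

#' Canonical k-mer set of a sequence
#'
#' Enumerates all length-\code{k} windows of the sequence, replaces each by
#' the lexicographically smaller of itself and its reverse complement (the
#' canonical form, which makes profiles strand-invariant), skips windows
#' containing N, and returns the distinct canonical k-mers.
#'
#' @param seq a single A/C/G/T/N character string or
#'   [Biostrings::DNAString].
#' @param k word length (>= 1, <= sequence length).
#' @return Character vector of distinct canonical k-mers.
#' @examples
#' canonicalKmers("AAAAA", 2)  # "AA" (its reverse complement "TT" is larger)
#' @export
canonicalKmers <- function(seq, k) {
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L) stop("'seq' must be a single sequence")
  n <- nchar(seq)
  if (k < 1L) stop("'k' must be >= 1")
  if (k > n) stop("'k' (", k, ") exceeds sequence length (", n, ")")
  if (!grepl("^[ACGTN]*$", seq))
    stop("sequence contains characters outside A/C/G/T/N")
  starts <- seq_len(n - k + 1L)
  fw <- substring(seq, starts, starts + k - 1L)
  if (grepl("N", seq, fixed = TRUE)) {
    fw <- fw[!grepl("N", fw, fixed = TRUE)]
    if (!length(fw)) return(character(0))
    rc <- vapply(fw, .revcomp, character(1), USE.NAMES = FALSE)
  } else {
    rcseq <- .revcomp(seq)
    rcStarts <- n - k + 2L - starts
    rc <- substring(rcseq, rcStarts, rcStarts + k - 1L)
  }
  canon <- ifelse(fw <= rc, fw, rc)
  unique(canon)
}

#' Binary (Jaccard) distance between two presence/absence sets
#'
#' The asymmetric binary distance: the size of the symmetric difference over
#' the size of the union. Joint absences are ignored; 0 iff the sets are
#' equal, 1 iff they are disjoint.
#'
#' @param a,b character vectors (presence sets, e.g. canonical k-mers or gene
#'   family ids). Both empty is undefined and raises an error.
#' @return Distance in \[0, 1\].
#' @examples
#' binaryDistance(c("x", "y", "z"), "x")  # 2/3
#' @export
binaryDistance <- function(a, b) {
  a <- unique(a); b <- unique(b)
  nu <- length(union(a, b))
  if (nu == 0) stop("binary distance is undefined for two empty sets")
  ni <- length(intersect(a, b))
  (nu - ni) / nu
}

#' Pairwise canonical k-mer distance matrix
#'
#' Profiles every genome with [canonicalKmers()] and computes all pairwise
#' binary (Jaccard) distances. Deterministic; label order follows input
#' order.
#'
#' @param genomes named [Biostrings::DNAStringSet] (or named character
#'   vector) of >= 2 genomes with unique ids.
#' @param k word length (default 10; 21 is the other conventional choice).
#' @return A \code{dist} with genome ids as labels.
#' @export
kmerDistanceMatrix <- function(genomes, k = 10L) {
  ids <- names(genomes)
  seqs <- stats::setNames(as.character(genomes), ids)
  if (length(seqs) < 2L) stop("need at least 2 genomes")
  if (is.null(ids) || anyDuplicated(ids))
    stop("genomes must have unique ids")
  profiles <- lapply(seqs, canonicalKmers, k = k)
  n <- length(profiles)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- binaryDistance(profiles[[i]], profiles[[j]])
    }
  }
  stats::as.dist(m)
}
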