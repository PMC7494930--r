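# Topological and branch-length agreement between phylogenetic trees.

.checkLeafSets <- function(t1, t2) {
  a <- sort(t1$tip.label); b <- sort(t2$tip.label)
  if (!identical(a, b)) {
    only1 <- setdiff(a, b); only2 <- setdiff(b, a)
    stop("leaf sets differ; only in tree 1: ",
         paste(only1, collapse = ", "), "; only in tree 2: ",
         paste(only2, collapse = ", "))
  }
}

#' Robinson-Foulds distance between two trees
#'
#' The number of non-trivial bipartitions (internal edges) present in exactly
#' one of the two unrooted trees. Rooted inputs are unrooted first (the
#' degree-2 root is suppressed).
#'
#' @param t1,t2 [ape::phylo] trees over the same leaf set.
#' @return Integer RF distance.
#' @export
rfDistance <- function(t1, t2) {
  .checkLeafSets(t1, t2)
  b1 <- names(.bipartitions(t1))
  b2 <- names(.bipartitions(t2))
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Branch-score (Kuhner-Felsenfeld) distance between two trees
#'
#' The square root of the sum, over the union of bipartitions of the two
#' trees (pendant edges included), of squared branch-length differences; a
#' bipartition absent from one tree contributes its full squared length.
#'
#' @param t1,t2 [ape::phylo] trees with branch lengths over the same leaf
#'   set.
#' @return Non-negative numeric.
#' @export
branchScore <- function(t1, t2) {
  .checkLeafSets(t1, t2)
  b1 <- .bipartitions(t1, includeTrivial = TRUE)
  b2 <- .bipartitions(t2, includeTrivial = TRUE)
  keys <- union(names(b1), names(b2))
  l1 <- ifelse(keys %in% names(b1), b1[keys], 0)
  l2 <- ifelse(keys %in% names(b2), b2[keys], 0)
  sqrt(sum((l1 - l2)^2))
}

#' Summary of tree agreement
#'
#' Computes the Robinson-Foulds distance, its maximum 2(n-3) for binary
#' unrooted trees, the normalized RF, and the branch-score distance.
#'
#' @param t1,t2 [ape::phylo] trees over the same leaf set.
#' @return A one-row data.frame: \code{rf}, \code{rf_max},
#'   \code{normalized_rf}, \code{branch_score}.
#' @export
compareTrees <- function(t1, t2) {
  rf <- rfDistance(t1, t2)
  n <- length(t1$tip.label)
  rfMax <- max(2L * (n - 3L), 0L)
  data.frame(
    rf = rf, rf_max = rfMax,
    normalized_rf = if (rfMax > 0) rf / rfMax else 0,
    branch_score = branchScore(t1, t2))
}

#' Convert a dendrogram to an unrooted phylo tree
#'
#' Converts a [stats::hclust] (e.g. from [upgma()]) to an [ape::phylo] with
#' heights as branch lengths, then suppresses the degree-2 root so the result
#' is comparable to unrooted marker trees.
#'
#' @param hc a [stats::hclust].
#' @return An unrooted [ape::phylo].
#' @export
dendrogramToPhylo <- function(hc) {
  ape::unroot(ape::as.phylo(hc))
}
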