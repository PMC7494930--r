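# UPGMA dendrograms and cut-height cluster calling.
#
# Merge heights are the average inter-cluster distances themselves (not
# halved), the convention of standard hierarchical clustering under which
# published cut-off heights on binary-distance dendrograms (0.82, 0.81, 0.58,
# 0.52, 0.39, 0.36 and the like) are read directly off the tree.

#' UPGMA (average linkage) dendrogram
#'
#' Agglomerates the distance matrix by unweighted pair group method with
#' arithmetic mean. Each merge is placed at the average distance between the
#' two merged groups, so heights are directly comparable to published binary
#' distance cut-offs.
#'
#' @param d a \code{dist} (or symmetric matrix) with >= 2 labelled items and
#'   no missing values.
#' @return A [stats::hclust] object (ultrametric; \code{method = "average"}).
#' @export
upgma <- function(d) {
  d <- stats::as.dist(d)
  if (attr(d, "Size") < 2L) stop("need at least 2 items")
  if (anyNA(d)) stop("distance matrix contains NA/NaN")
  stats::hclust(d, method = "average")
}

# Cluster membership from merges strictly below `height` (union-find over the
# hclust merge list).
.cutStrict <- function(hc, height) {
  n <- length(hc$labels)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  groupOf <- integer(nrow(hc$merge))  # root item index of each merge node
  for (k in seq_len(max(nrow(hc$merge), 0L))) {
    a <- hc$merge[k, 1]; b <- hc$merge[k, 2]
    ia <- if (a < 0) -a else groupOf[a]
    ib <- if (b < 0) -b else groupOf[b]
    ra <- find(ia); rb <- find(ib)
    if (hc$height[k] < height) parent[rb] <- ra
    groupOf[k] <- ra  # node location regardless of whether merge applied
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(hc$labels, roots)
}

# Order clusters by decreasing size, ties by lexicographically smallest
# member, and label A, B, C, ...
.labelClusters <- function(groups, prefix = NULL) {
  smallest <- vapply(groups, function(g) min(g), character(1))
  ord <- order(-lengths(groups), smallest)
  groups <- groups[ord]
  labels <- if (is.null(prefix)) .clusterLetters(length(groups))
            else paste0(prefix, seq_along(groups))
  out <- rep(labels, lengths(groups))
  names(out) <- unlist(groups, use.names = FALSE)
  out
}

#' Cut a dendrogram at a fixed height into labelled clusters
#'
#' Clusters are the maximal groups whose internal merge heights are all
#' strictly below \code{height}. Labels are assigned by decreasing cluster
#' size (ties by lexicographically smallest member): A, B, C, ... Letter
#' identity is a presentation choice; only the partition itself is
#' meaningful.
#'
#' @param hc a [stats::hclust], e.g. from [upgma()].
#' @param height cut height (>= 0).
#' @return Named character vector: item -> cluster label, with the cut height
#'   in \code{attr(, "cut_height")}.
#' @export
cutDendrogram <- function(hc, height) {
  if (height < 0) stop("'height' must be >= 0")
  out <- .labelClusters(.cutStrict(hc, height))
  out <- out[hc$labels]
  attr(out, "cut_height") <- height
  out
}

#' Refine a cluster assignment at a lower cut height
#'
#' Cuts the same dendrogram at \code{lowerHeight} and nests the resulting
#' subclusters inside the parent assignment: a parent cluster X that splits
#' gains labels X1, X2, ... (by decreasing subcluster size); an unsplit
#' parent keeps its label. Every subcluster is a subset of exactly one parent
#' cluster.
#'
#' @param hc the [stats::hclust] the parent assignment was cut from.
#' @param parent named character vector from [cutDendrogram()].
#' @param lowerHeight refinement height, strictly below the parent cut.
#' @return Named character vector of nested labels with
#'   \code{attr(, "cut_height")}.
#' @export
subcluster <- function(hc, parent, lowerHeight) {
  parentHeight <- attr(parent, "cut_height")
  if (!is.null(parentHeight) && lowerHeight >= parentHeight)
    stop("'lowerHeight' must be strictly below the parent cut height")
  groups <- .cutStrict(hc, lowerHeight)
  out <- character(0)
  for (lab in unique(parent[hc$labels])) {
    members <- names(parent)[parent == lab]
    sub <- Filter(function(g) g[1] %in% members, groups)
    out <- c(out, if (length(sub) == 1L) stats::setNames(rep(lab, length(sub[[1]])), sub[[1]])
             else .labelClusters(sub, prefix = lab))
  }
  out <- out[hc$labels]
  attr(out, "cut_height") <- lowerHeight
  out
}

#' Cophenetic distances of a dendrogram
#'
#' @param hc a [stats::hclust].
#' @return A \code{dist} of merge heights at which each pair first joins.
#' @export
copheneticDistances <- function(hc) stats::cophenetic(hc)
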