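# Marker-gene phylogenies: progressive multiple alignment, Tamura-Nei (1993)
# pairwise distances, Saitou-Nei neighbor joining, and nonparametric
# bootstrap supports.
#
# Distance-based NJ on TN93 distances stands in for likelihood tree
# inference: it is deterministic, fast at marker-gene scale, exact on
# additive distances, and sufficient for cluster-level conclusions; this is
# the package's one intentional methodological substitution and is documented
# in the vignette.

#' @useDynLib phagepop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.profileCounts <- function(rows) {
  chars <- strsplit(rows, "", fixed = TRUE)
  L <- length(chars[[1]])
  m <- matrix(0, nrow = 5, ncol = L,
              dimnames = list(c(BASES, "-"), NULL))
  for (v in chars) {
    idx <- match(v, c(BASES, "-"))
    m[cbind(idx, seq_len(L))] <- m[cbind(idx, seq_len(L))] + 1
  }
  m / length(rows)
}

.applyPath <- function(rows, idx) {
  out <- vapply(strsplit(rows, "", fixed = TRUE), function(v) {
    o <- rep("-", length(idx))
    o[idx > 0] <- v[idx[idx > 0]]
    paste(o, collapse = "")
  }, character(1))
  out
}

#' Progressive multiple alignment of marker-gene sequences
#'
#' Simple progressive aligner: the guide tree is a UPGMA dendrogram of
#' pairwise p-distances from global pairwise alignments; profiles are then
#' merged leaf-to-root by global profile-profile alignment with affine gaps
#' (match +1, mismatch -1, gap open -5, gap extend -1). Deterministic.
#'
#' @param seqs named [Biostrings::DNAStringSet] (or named character) of >= 2
#'   ACGT sequences.
#' @return A named character vector of equal-length gapped sequences (rows in
#'   input order); de-gapping row i returns input sequence i.
#' @export
progressiveAlign <- function(seqs) {
  ids <- names(seqs)
  seqs <- stats::setNames(as.character(seqs), ids)
  if (length(seqs) < 2L) stop("need at least 2 sequences to align")
  if (is.null(ids) || anyDuplicated(ids))
    stop("sequences must have unique names")
  if (!all(grepl("^[ACGT]+$", seqs)))
    stop("sequences must be non-empty and ACGT only")
  n <- length(seqs)
  if (n == 2L) {
    merged <- .mergeProfiles(seqs[1], seqs[2])
    return(stats::setNames(merged, ids))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  pd <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      aln <- Biostrings::pairwiseAlignment(seqs[i], seqs[j], type = "global",
                                           substitutionMatrix = mat,
                                           gapOpening = 5, gapExtension = 1)
      alnLen <- nchar(as.character(Biostrings::alignedPattern(aln)))
      pd[i, j] <- pd[j, i] <- 1 - Biostrings::nmatch(aln) / alnLen
    }
  }
  hc <- upgma(stats::as.dist(pd))
  nodes <- vector("list", nrow(hc$merge))
  getNode <- function(ref) {
    if (ref < 0) list(ids = ids[-ref], rows = unname(seqs[-ref]))
    else nodes[[ref]]
  }
  for (k in seq_len(nrow(hc$merge))) {
    a <- getNode(hc$merge[k, 1]); b <- getNode(hc$merge[k, 2])
    path <- .cppAlignProfiles(.profileCounts(a$rows), .profileCounts(b$rows),
                              1, -1, 5, 1)
    nodes[[k]] <- list(
      ids = c(a$ids, b$ids),
      rows = c(.applyPath(a$rows, path$a), .applyPath(b$rows, path$b)))
  }
  final <- nodes[[nrow(hc$merge)]]
  out <- stats::setNames(final$rows, final$ids)[ids]
  out
}

.mergeProfiles <- function(s1, s2) {
  path <- .cppAlignProfiles(.profileCounts(s1), .profileCounts(s2),
                            1, -1, 5, 1)
  c(.applyPath(s1, path$a), .applyPath(s2, path$b))
}

# Encode gapped rows as integer matrix (A=1..T=4, gap/other=0).
.encodeAlignment <- function(rows) {
  chars <- strsplit(rows, "", fixed = TRUE)
  L <- unique(lengths(chars))
  if (length(L) != 1L) stop("alignment rows differ in length")
  m <- do.call(rbind, lapply(chars, function(v) {
    i <- match(v, BASES)
    i[is.na(i)] <- 0L
    i
  }))
  rownames(m) <- names(rows)
  m
}

#' Tamura-Nei (1993) distance between two aligned sequences
#'
#' Closed-form TN93 distance with pairwise deletion: columns where either row
#' has a gap or ambiguous base are excluded for that pair. Base frequencies
#' are pooled over the two rows. The model distinguishes purine transitions
#' (A<->G, proportion P1), pyrimidine transitions (C<->T, P2) and
#' transversions (Q).
#'
#' @param rowA,rowB equal-length gapped sequences (character scalars).
#' @return A list of class \code{"tn93"}: \code{d} (substitutions/site),
#'   \code{P1}, \code{P2}, \code{Q}, \code{freqs} (named A/C/G/T), and
#'   \code{sites} (columns used).
#' @export
tn93Distance <- function(rowA, rowB) {
  m <- .encodeAlignment(c(a = rowA, b = rowB))
  .tn93Pair(m[1, ], m[2, ])
}

.tn93Pair <- function(xi, xj) {
  ok <- xi > 0L & xj > 0L
  if (!any(ok)) stop("no usable (gap-free) columns for this pair")
  xi <- xi[ok]; xj <- xj[ok]
  nSites <- length(xi)
  P1 <- sum((xi == 1L & xj == 3L) | (xi == 3L & xj == 1L)) / nSites
  P2 <- sum((xi == 2L & xj == 4L) | (xi == 4L & xj == 2L)) / nSites
  Q <- sum(xi != xj) / nSites - P1 - P2
  cnt <- tabulate(xi, 4L) + tabulate(xj, 4L)
  f <- cnt / sum(cnt)
  names(f) <- BASES
  gA <- f[["A"]]; gC <- f[["C"]]; gG <- f[["G"]]; gT <- f[["T"]]
  gR <- gA + gG; gY <- gC + gT
  k1 <- if (gR > 0) 2 * gA * gG / gR else 0
  k2 <- if (gY > 0) 2 * gC * gT / gY else 0
  k3 <- 2 * (gR * gY -
               (if (gR > 0) gA * gG * gY / gR else 0) -
               (if (gY > 0) gC * gT * gR / gY else 0))
  term <- function(k, p, qdiv) {
    if (k <= 0) {
      if (p > 0) stop("saturated pair: transition class with zero ",
                      "expected frequency")
      return(0)
    }
    arg <- 1 - p / k - Q / qdiv
    if (arg <= 0) stop("saturated pair: TN93 logarithm argument <= 0")
    -k * log(arg)
  }
  d1 <- term(k1, P1, 2 * gR)
  d2 <- term(k2, P2, 2 * gY)
  d3 <- if (k3 <= 0) 0 else {
    arg <- 1 - Q / (2 * gR * gY)
    if (arg <= 0) stop("saturated pair: TN93 logarithm argument <= 0")
    -k3 * log(arg)
  }
  structure(list(d = d1 + d2 + d3, P1 = P1, P2 = P2, Q = Q, freqs = f,
                 sites = nSites), class = "tn93")
}

#' @export
print.tn93 <- function(x, ...) {
  cat(sprintf("TN93 distance: %.6f subs/site (P1=%.4f P2=%.4f Q=%.4f, %d sites)\n",
              x$d, x$P1, x$P2, x$Q, x$sites))
  invisible(x)
}

#' Pairwise TN93 distance matrix of an alignment
#'
#' @param aln named character vector of equal-length gapped rows (from
#'   [progressiveAlign()]).
#' @return A \code{dist} of TN93 distances (pairwise deletion).
#' @export
tn93DistanceMatrix <- function(aln) {
  m <- .encodeAlignment(aln)
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      out[i, j] <- out[j, i] <- .tn93Pair(m[i, ], m[j, ])$d
    }
  }
  stats::as.dist(out)
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining with deterministic tie-breaking (candidate
#' pairs at equal Q-criterion are resolved by label order). Negative branch
#' lengths are clamped to zero with the deficit transferred to the sister
#' branch of the join.
#'
#' @param d a \code{dist} (or symmetric matrix) over >= 3 labelled taxa.
#' @return An unrooted [ape::phylo] tree.
#' @export
njTree <- function(d) {
  D <- as.matrix(stats::as.dist(d))
  if (anyNA(D)) stop("distance matrix contains NA/NaN")
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs >= 3 taxa")
  labels <- rownames(D)
  nwk <- labels                 # newick fragment per active node
  key <- labels                 # smallest original label, for tie-breaks
  fmt <- function(x) sprintf("%.10g", x)
  while (nrow(D) > 3L) {
    nn <- nrow(D)
    r <- rowSums(D)
    Qm <- (nn - 2) * D - outer(r, r, "+")
    diag(Qm) <- Inf
    best <- which(Qm == min(Qm), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    pick <- order(key[best[, 1]], key[best[, 2]])[1]
    i <- best[pick, 1]; j <- best[pick, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (nn - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newD <- (D[i, ] + D[j, ] - D[i, j]) / 2
    merged <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(li), nwk[j], fmt(lj))
    mergedKey <- min(key[i], key[j])
    keep <- setdiff(seq_len(nn), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newD[keep]),
               c(newD[keep], 0))
    nwk <- c(nwk[keep], merged)
    key <- c(key[keep], mergedKey)
    rownames(D) <- colnames(D) <- key
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 nwk[1], fmt(la), nwk[2], fmt(lb), nwk[3], fmt(lc))
  ape::read.tree(text = txt)
}

# Non-trivial bipartitions of an unrooted tree, keyed canonically (the side
# not containing the alphabetically first tip, sorted and joined by "|").
# Returns a named numeric vector key -> branch length, plus tip-edge entries
# when `includeTrivial`.
.bipartitions <- function(tree, includeTrivial = FALSE) {
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  refTip <- sort(tree$tip.label)[1]
  tr <- ape::reorder.phylo(tree, "postorder")
  tips <- vector("list", n + tr$Nnode)
  for (i in seq_len(n)) tips[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; c0 <- tr$edge[e, 2]
    tips[[p]] <- c(tips[[p]], tips[[c0]])
  }
  out <- numeric(0)
  for (e in seq_len(nrow(tr$edge))) {
    child <- tr$edge[e, 2]
    side <- tips[[child]]
    sz <- length(side)
    if (!includeTrivial && (sz < 2L || sz > n - 2L)) next
    if (refTip %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) == 0L || length(side) == n) next
    key <- paste(sort(side), collapse = "|")
    len <- if (is.null(tr$edge.length)) NA_real_ else tr$edge.length[e]
    out[key] <- if (key %in% names(out)) out[key] + len else len
  }
  out
}

#' Bootstrap supports for a marker-gene NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds a TN93 + NJ tree
#' per replicate, and reports for each internal bipartition of the
#' point-estimate tree the percentage of replicate trees containing it.
#' Supports are attached as integer internal node labels. Replicates in which
#' a pair saturates (TN93 undefined) are dropped from the denominator;
#' seed-deterministic.
#'
#' @param aln named character vector of gapped rows.
#' @param nReplicates number of bootstrap replicates (>= 1; 1000 by
#'   convention).
#' @param seed integer RNG seed.
#' @return The point-estimate [ape::phylo] with \code{node.label} supports
#'   (root label empty) and the support table in \code{attr(, "supports")}.
#' @export
bootstrapSupport <- function(aln, nReplicates = 1000L, seed = 1L) {
  if (nReplicates < 1L) stop("'nReplicates' must be >= 1")
  m <- .encodeAlignment(aln)
  tree <- njTree(tn93DistanceMatrix(aln))
  target <- .bipartitions(tree)
  hits <- stats::setNames(rep(0L, length(target)), names(target))
  set.seed(seed)
  nOk <- 0L
  L <- ncol(m)
  for (rep in seq_len(nReplicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    mr <- m[, cols, drop = FALSE]
    dm <- tryCatch({
      n <- nrow(mr)
      out <- matrix(0, n, n, dimnames = list(rownames(mr), rownames(mr)))
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          out[i, j] <- out[j, i] <- .tn93Pair(mr[i, ], mr[j, ])$d
        }
      }
      stats::as.dist(out)
    }, error = function(e) NULL)
    if (is.null(dm)) next
    nOk <- nOk + 1L
    repBip <- names(.bipartitions(njTree(dm)))
    found <- names(target) %in% repBip
    hits[found] <- hits[found] + 1L
  }
  if (nOk == 0L) stop("all bootstrap replicates saturated")
  support <- round(100 * hits / nOk)
  # attach as node labels: find the internal node of each bipartition
  tree2 <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  n <- length(tree2$tip.label)
  refTip <- sort(tree2$tip.label)[1]
  tr <- ape::reorder.phylo(tree2, "postorder")
  tips <- vector("list", n + tr$Nnode)
  for (i in seq_len(n)) tips[[i]] <- tree2$tip.label[i]
  labs <- rep("", tr$Nnode)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; c0 <- tr$edge[e, 2]
    tips[[p]] <- c(tips[[p]], tips[[c0]])
    if (c0 > n) {
      side <- tips[[c0]]
      if (refTip %in% side) side <- setdiff(tree2$tip.label, side)
      key <- paste(sort(side), collapse = "|")
      if (key %in% names(support))
        labs[c0 - n] <- as.character(support[[key]])
    }
  }
  tree2$node.label <- labs
  attr(tree2, "supports") <- support
  attr(tree2, "replicates_used") <- nOk
  tree2
}
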