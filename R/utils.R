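# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# Reverse complement of a plain character string.
.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Round half away from zero (printed-table convention; R's round() is
# round-half-even).
.roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Cluster labels A, B, ..., Z, AA, AB, ... for arbitrary n.
.clusterLetters <- function(n) {
  if (n <= 26) return(LETTERS[seq_len(n)])
  c(LETTERS, as.vector(t(outer(LETTERS, LETTERS, paste0))))[seq_len(n)]
}

# G+C fraction of a character string (N excluded from the denominator).
.gcFraction <- function(s) {
  cnt <- table(strsplit(s, "", fixed = TRUE)[[1]])
  acgt <- sum(cnt[intersect(names(cnt), BASES)])
  if (acgt == 0) stop("sequence has no A/C/G/T bases")
  sum(cnt[intersect(names(cnt), c("G", "C"))]) / acgt
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two cluster assignments of the same
#' items: 1 for identical partitions (up to label permutation), about 0 for
#' independent random partitions.
#'
#' @param x,y cluster labels (vectors of equal length; names, if present on
#'   both, are used to align items).
#' @return A single numeric value (<= 1).
#' @examples
#' adjustedRandIndex(c(1, 1, 2, 2), c("a", "a", "b", "b")) # 1
#' @export
adjustedRandIndex <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    if (!setequal(names(x), names(y)))
      stop("'x' and 'y' must be labelings of the same items")
    y <- y[names(x)]
  }
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  tab <- table(x, y)
  n <- length(x)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  expected <- sumi * sumj / choose(n, 2)
  maxidx <- (sumi + sumj) / 2
  if (maxidx == expected) return(1)  # both partitions trivial
  (sumij - expected) / (maxidx - expected)
}
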