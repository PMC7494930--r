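# Gene-order locally collinear blocks (LCBs): maximal runs of consecutive
# shared gene families with consistent order and orientation across two or
# more genomes — a gene-level analogue of whole-genome-alignment collinear
# blocks, testable against simulator truth.
#
# Algorithm (adjacency-breakpoint chaining):
#   1. every family is profiled by the set of genomes containing it; families
#      with different genome sets can never share a block (a module lost in
#      one genome splits its flanks into separate blocks);
#   2. within a genome-set class, consecutive occurrences in a reference
#      genome are chained when, in EVERY genome of the class, every
#      occurrence of either family is immediately adjacent to the other (in
#      full gene order) with consistent relative orientation — an inversion
#      or translocation in any member breaks the chain there;
#   3. maximal chains are blocks; identical chains found at several places
#      (tandem repeats) become multiple occurrences of one block, one per
#      copy.

#' Find gene-order locally collinear blocks
#'
#' @param annot [GenomicRanges::GRanges] of genes across >= 2 genomes with
#'   metadata columns \code{gene_id} and \code{family_id} (every gene must be
#'   assigned a family).
#' @param minBlockGenes minimum genes per block (default 2: a single shared
#'   gene is not evidence of collinearity).
#' @return A list with \code{blocks} (data.frame: \code{block_id},
#'   \code{n_genes}, \code{n_genomes}, \code{families} — signed family
#'   string) and \code{occurrences} (data.frame: \code{block_id},
#'   \code{genome_id}, \code{start_index}, \code{end_index} — 1-based gene
#'   ranks within the genome — and \code{orientation} +1/-1).
#' @export
findLcbs <- function(annot, minBlockGenes = 2L) {
  fam <- mcols(annot)$family_id
  if (is.null(fam) || anyNA(fam) || any(!nzchar(fam)))
    stop("every gene must have an assigned family_id")
  gid <- as.character(seqnames(annot))
  ord <- order(gid, start(annot))
  genomesList <- split(seq_along(annot)[ord], gid[ord])
  # per-genome ordered family / sign vectors
  gfam <- lapply(genomesList, function(i) fam[i])
  gsign <- lapply(genomesList, function(i)
    ifelse(as.character(strand(annot))[i] == "-", -1L, 1L))
  famSet <- lapply(split(gid, fam), function(g) sort(unique(g)))
  sig <- vapply(famSet, paste, character(1), collapse = "|")

  # adjacency validity: every occurrence of a is adjacent to b (and vice
  # versa) in every genome of the shared set, with consistent orientation
  adjacentEverywhere <- function(a, b, sa, sb, genomesIn) {
    for (g in genomesIn) {
      f <- gfam[[g]]; s <- gsign[[g]]
      posA <- which(f == a); posB <- which(f == b)
      okA <- vapply(posA, function(p) {
        (p < length(f) && f[p + 1] == b && s[p] == sa && s[p + 1] == sb) ||
          (p > 1 && f[p - 1] == b && s[p] == -sa && s[p - 1] == -sb)
      }, logical(1))
      okB <- vapply(posB, function(p) {
        (p > 1 && f[p - 1] == a && s[p] == sb && s[p - 1] == sa) ||
          (p < length(f) && f[p + 1] == a && s[p] == -sb && s[p + 1] == -sa)
      }, logical(1))
      if (!all(okA) || !all(okB)) return(FALSE)
    }
    TRUE
  }

  # collect candidate chains (signed family sequences) per genome-set class
  chains <- list()
  for (s in unique(sig)) {
    genomesIn <- famSet[[match(s, sig)]]
    if (length(genomesIn) < 2L) next
    classFams <- names(sig)[sig == s]
    ref <- genomesIn[1]
    f <- gfam[[ref]]; sgn <- gsign[[ref]]
    occ <- which(f %in% classFams)
    if (!length(occ)) next
    # chain consecutive class occurrences that are full-order adjacent in the
    # reference and adjacency-consistent in every member genome
    runStart <- 1L
    runs <- list()
    if (length(occ) > 1L) {
      for (t in seq_len(length(occ) - 1L)) {
        p <- occ[t]; q <- occ[t + 1L]
        ok <- (q == p + 1L) &&
          adjacentEverywhere(f[p], f[q], sgn[p], sgn[q], genomesIn)
        if (!ok) {
          runs[[length(runs) + 1L]] <- occ[runStart:t]
          runStart <- t + 1L
        }
      }
    }
    runs[[length(runs) + 1L]] <- occ[runStart:length(occ)]
    for (r in runs) {
      if (length(r) < minBlockGenes) next
      chains[[length(chains) + 1L]] <- list(
        fams = f[r], signs = sgn[r], genomes = genomesIn)
    }
  }
  if (!length(chains)) {
    return(list(
      blocks = data.frame(block_id = character(0), n_genes = integer(0),
                          n_genomes = integer(0), families = character(0)),
      occurrences = data.frame(block_id = character(0),
                               genome_id = character(0),
                               start_index = integer(0),
                               end_index = integer(0),
                               orientation = integer(0))))
  }

  # canonical content key (forward vs reverse-complement, lexicographic min)
  contentKey <- function(fams, signs) {
    fwd <- paste(paste0(fams, ifelse(signs > 0, "(+)", "(-)")),
                 collapse = ",")
    rev <- paste(paste0(rev(fams), ifelse(rev(-signs) > 0, "(+)", "(-)")),
                 collapse = ",")
    if (fwd <= rev) fwd else rev
  }
  keys <- vapply(chains, function(ch) contentKey(ch$fams, ch$signs),
                 character(1))
  uniq <- !duplicated(keys)
  chains <- chains[uniq]
  ord2 <- order(-lengths(lapply(chains, `[[`, "fams")),
                vapply(chains, function(ch) ch$fams[1], character(1)))
  chains <- chains[ord2]

  # locate occurrences, longest blocks first; a gene joins at most one block
  consumed <- lapply(gfam, function(f) logical(length(f)))
  blocks <- list(); occurrences <- list()
  for (bi in seq_along(chains)) {
    ch <- chains[[bi]]
    bid <- sprintf("LCB%03d", bi)
    L <- length(ch$fams)
    for (g in ch$genomes) {
      f <- gfam[[g]]; s <- gsign[[g]]
      if (L > length(f)) next
      for (p in seq_len(length(f) - L + 1L)) {
        idx <- p:(p + L - 1L)
        if (any(consumed[[g]][idx])) next
        if (all(f[idx] == ch$fams) && all(s[idx] == ch$signs)) {
          orient <- 1L
        } else if (all(f[idx] == rev(ch$fams)) &&
                   all(s[idx] == rev(-ch$signs))) {
          orient <- -1L
        } else next
        consumed[[g]][idx] <- TRUE
        occurrences[[length(occurrences) + 1L]] <- data.frame(
          block_id = bid, genome_id = g, start_index = p,
          end_index = p + L - 1L, orientation = orient,
          stringsAsFactors = FALSE)
      }
    }
    blocks[[bi]] <- data.frame(
      block_id = bid, n_genes = L,
      n_genomes = length(unique(vapply(
        occurrences[vapply(occurrences, function(o) o$block_id[1] == bid,
                           logical(1))],
        function(o) o$genome_id[1], character(1)))),
      families = paste(paste0(ch$fams, ifelse(ch$signs > 0, "(+)", "(-)")),
                       collapse = ","),
      stringsAsFactors = FALSE)
  }
  list(blocks = do.call(rbind, blocks),
       occurrences = do.call(rbind, occurrences))
}

#' Per-genome LCB census
#'
#' @param lcbs result of [findLcbs()].
#' @param genomeIds optional character vector of genomes to tabulate
#'   (defaults to genomes with at least one block occurrence).
#' @return A list with \code{counts} (named integer, block occurrences per
#'   genome) and \code{presence} (binary matrix, blocks x genomes).
#' @export
lcbCensus <- function(lcbs, genomeIds = NULL) {
  occ <- lcbs$occurrences
  if (is.null(genomeIds)) genomeIds <- sort(unique(occ$genome_id))
  counts <- stats::setNames(integer(length(genomeIds)), genomeIds)
  tab <- table(occ$genome_id)
  counts[names(tab)] <- as.integer(tab)
  blockIds <- lcbs$blocks$block_id
  pres <- matrix(0L, nrow = length(blockIds), ncol = length(genomeIds),
                 dimnames = list(blockIds, genomeIds))
  if (nrow(occ))
    pres[cbind(match(occ$block_id, blockIds),
               match(occ$genome_id, genomeIds))] <- 1L
  list(counts = counts, presence = pres)
}
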