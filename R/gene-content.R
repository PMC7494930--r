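# Ortholog family clustering, gene presence/absence matrices, gene-content
# distances and the core/softcore/shell/cloud pan-genome partition.
#
# Families are built by deterministic greedy incremental clustering at a
# global nucleotide identity threshold (default 90%, the conventional
# pan-genome setting): genes are processed longest-first (ties by gene id)
# and each joins the first existing family whose representative it matches at
# >= the threshold, else founds a new family. Identity is matches / alignment
# length under global alignment with match +1, mismatch -1, gap -2, so gaps
# count against identity.

.identityScreenK <- 12L

# Global nucleotide identity (matches / alignment length) for one pair.
.globalIdentity <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 2)
  alnLen <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / alnLen
}

# Cheap lower-bound screen: fraction of the shorter sequence's k-mers shared.
# At >= 90% identity the expected shared fraction is ~0.9^12 ~ 0.28; pairs
# below 0.05 cannot plausibly reach the threshold and skip the alignment.
.kmerContainment <- function(kA, kB) {
  length(intersect(kA, kB)) / min(length(kA), length(kB))
}

.fwdKmers <- function(s, k = .identityScreenK) {
  n <- nchar(s)
  if (n < k) return(s)
  starts <- seq_len(n - k + 1L)
  unique(substring(s, starts, starts + k - 1L))
}

#' Cluster genes into ortholog families by greedy identity clustering
#'
#' @param geneSeqs [Biostrings::DNAStringSet] of strand-corrected gene
#'   sequences, named by gene id (see [extractGeneSequences()]).
#' @param genomeIds character vector, the genome of each gene (same order as
#'   \code{geneSeqs}).
#' @param identityThreshold global nucleotide identity threshold in (0, 1\];
#'   default 0.90.
#' @return A data.frame with one row per gene: \code{gene_id},
#'   \code{genome_id}, \code{family_id}, \code{representative} (logical,
#'   TRUE for the gene that founded the family).
#' @export
clusterGeneFamilies <- function(geneSeqs, genomeIds,
                                identityThreshold = 0.90) {
  if (length(geneSeqs) == 0L) stop("empty gene set")
  if (length(genomeIds) != length(geneSeqs))
    stop("'genomeIds' must parallel 'geneSeqs'")
  ids <- names(geneSeqs)
  if (is.null(ids) || anyDuplicated(ids))
    stop("gene sequences must have unique names")
  seqs <- as.character(geneSeqs)
  ord <- order(-nchar(seqs), ids)
  repSeq <- character(0)
  repLen <- integer(0)
  repKmers <- list()
  fam <- character(length(seqs))
  isRep <- logical(length(seqs))
  for (i in ord) {
    s <- seqs[i]
    len <- nchar(s)
    assigned <- NA_integer_
    if (length(repSeq)) {
      # genes are processed longest-first, so representatives are never
      # shorter-scaled beyond the length-ratio bound identity <= min/max
      cand <- which(len / repLen >= identityThreshold)
      if (length(cand)) {
        km <- .fwdKmers(s)
        for (j in cand) {
          if (.kmerContainment(km, repKmers[[j]]) < 0.05) next
          if (.globalIdentity(s, repSeq[j]) >= identityThreshold) {
            assigned <- j
            break
          }
        }
      }
    }
    if (is.na(assigned)) {
      repSeq <- c(repSeq, s)
      repLen <- c(repLen, len)
      repKmers[[length(repSeq)]] <- .fwdKmers(s)
      assigned <- length(repSeq)
      isRep[i] <- TRUE
    }
    fam[i] <- sprintf("GF%05d", assigned)
  }
  data.frame(gene_id = ids, genome_id = genomeIds, family_id = fam,
             representative = isRep, stringsAsFactors = FALSE)
}

#' Gene presence/absence matrix
#'
#' @param families data.frame from [clusterGeneFamilies()] (columns
#'   \code{genome_id}, \code{family_id}), or any per-gene table with those
#'   columns (e.g. truth annotations).
#' @param genomeIds optional character vector fixing row order (and including
#'   genomes with zero genes); defaults to order of appearance.
#' @return A binary integer matrix, genomes x families; paralogs collapse to
#'   a single presence.
#' @export
presenceAbsenceMatrix <- function(families, genomeIds = NULL) {
  if (is.null(genomeIds)) genomeIds <- unique(families$genome_id)
  famIds <- sort(unique(families$family_id))
  m <- matrix(0L, nrow = length(genomeIds), ncol = length(famIds),
              dimnames = list(genomeIds, famIds))
  idx <- cbind(match(families$genome_id, genomeIds),
               match(families$family_id, famIds))
  m[idx[!is.na(idx[, 1]), , drop = FALSE]] <- 1L
  m
}

#' Binary gene-content distance matrix
#'
#' Jaccard distance over per-genome family sets (the same binary distance as
#' [binaryDistance()], applied to rows of the presence/absence matrix).
#'
#' @param pa binary matrix from [presenceAbsenceMatrix()] with >= 2 rows.
#' @return A \code{dist} with genome ids as labels.
#' @export
geneContentDistance <- function(pa) {
  if (nrow(pa) < 2L) stop("need at least 2 genomes")
  empty <- rownames(pa)[rowSums(pa) == 0]
  if (length(empty))
    stop("genome(s) with zero gene families: ", paste(empty, collapse = ", "))
  n <- nrow(pa)
  m <- matrix(0, n, n, dimnames = list(rownames(pa), rownames(pa)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      inter <- sum(pa[i, ] & pa[j, ])
      uni <- sum(pa[i, ] | pa[j, ])
      m[i, j] <- m[j, i] <- (uni - inter) / uni
    }
  }
  stats::as.dist(m)
}

#' Core/softcore/shell/cloud pan-genome partition
#'
#' Classifies each gene family by its prevalence p (fraction of genomes
#' containing it): core p >= 0.99, softcore 0.95 <= p < 0.99, shell
#' 0.15 <= p < 0.95, cloud p < 0.15 (the Roary convention). The core genome
#' percentage is 100 * (core + softcore) / pan, rounded half-up to an
#' integer; the accessory percentage is the shell + cloud complement. Note
#' that with fewer than 20 genomes the 0.95/0.99 cut-points make "core" mean
#' "present in every genome".
#'
#' @param pa binary matrix from [presenceAbsenceMatrix()] with >= 2 rows.
#' @return A one-row data.frame: \code{n_genomes}, \code{core},
#'   \code{softcore}, \code{shell}, \code{cloud}, \code{pan},
#'   \code{core_pct}, \code{accessory_pct}.
#' @export
partitionPanGenome <- function(pa) {
  if (nrow(pa) < 2L) stop("need at least 2 genomes")
  p <- colMeans(pa > 0)
  core <- sum(p >= 0.99)
  softcore <- sum(p >= 0.95 & p < 0.99)
  shell <- sum(p >= 0.15 & p < 0.95)
  cloud <- sum(p < 0.15)
  pan <- length(p)
  data.frame(
    n_genomes = nrow(pa),
    core = core, softcore = softcore, shell = shell, cloud = cloud,
    pan = pan,
    core_pct = .roundHalfUp(100 * (core + softcore) / pan),
    accessory_pct = .roundHalfUp(100 * (shell + cloud) / pan))
}
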