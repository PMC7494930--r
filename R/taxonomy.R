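# ICTV-style genus assignment (nucleotide similarity > 50% to a classified
# reference) and printed-table population summaries.

#' Alignment-free nucleotide similarity between two genomes
#'
#' Sorensen-Dice coefficient over canonical k-mer sets:
#' \deqn{sim = 2 |K_a \cap K_b| / (|K_a| + |K_b|)}
#' a standard alignment-free proxy for whole-genome nucleotide similarity.
#' Symmetric; 1 for identical genomes; near 0 for unrelated ones.
#'
#' @param a,b genome sequences (character or [Biostrings::DNAString]).
#' @param k word length (default 21).
#' @return Similarity fraction in \[0, 1\].
#' @export
genomeSimilarity <- function(a, b, k = 21L) {
  ka <- canonicalKmers(a, k)
  kb <- canonicalKmers(b, k)
  2 * length(intersect(ka, kb)) / (length(ka) + length(kb))
}

#' Assign queries to genera by best-reference similarity
#'
#' Each query is compared to every reference genome with
#' [genomeSimilarity()]; the best-scoring reference (ties broken by reference
#' id) donates its genus (and family/subfamily, when provided) if the
#' similarity exceeds \code{threshold} — the conventional genus demarcation
#' of > 50% nucleotide similarity — otherwise the query is flagged
#' \code{NEW_GENUS_CANDIDATE}.
#'
#' @param queries named [Biostrings::DNAStringSet] (or named character).
#' @param references named [Biostrings::DNAStringSet] of >= 1 classified
#'   reference genomes.
#' @param refTaxa data.frame with columns \code{genome_id}, \code{genus} and
#'   optionally \code{family}, \code{subfamily}, covering all references.
#' @param threshold similarity threshold (default 0.50); assignment requires
#'   similarity strictly greater.
#' @param k word length for the similarity estimator.
#' @return A data.frame with one row per query: \code{genome_id},
#'   \code{best_reference}, \code{similarity}, \code{genus}, \code{family},
#'   \code{subfamily}.
#' @export
assignGenus <- function(queries, references, refTaxa, threshold = 0.50,
                        k = 21L) {
  if (length(references) < 1L) stop("empty reference set")
  if (!all(names(references) %in% refTaxa$genome_id))
    stop("refTaxa must cover every reference genome")
  qSeq <- stats::setNames(as.character(queries), names(queries))
  rSeq <- as.character(references)
  refIds <- names(references)
  refK <- lapply(rSeq, canonicalKmers, k = k)
  out <- lapply(names(qSeq), function(q) {
    kq <- canonicalKmers(qSeq[[q]], k)
    sims <- vapply(refK, function(kr)
      2 * length(intersect(kq, kr)) / (length(kq) + length(kr)), numeric(1))
    ord <- order(-sims, refIds)
    best <- ord[1]
    tax <- refTaxa[match(refIds[best], refTaxa$genome_id), , drop = FALSE]
    assigned <- sims[best] > threshold
    data.frame(
      genome_id = q,
      best_reference = refIds[best],
      similarity = sims[best],
      genus = if (assigned) tax$genus else "NEW_GENUS_CANDIDATE",
      family = if (assigned && "family" %in% names(tax))
        tax$family else NA_character_,
      subfamily = if (assigned && "subfamily" %in% names(tax))
        tax$subfamily else NA_character_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' G+C content of a sequence, in percent
#'
#' 100 * (G + C) / (A + C + G + T); N bases are excluded from the
#' denominator. Reported to one decimal.
#'
#' @param seq character or [Biostrings::DNAString] sequence.
#' @return Percentage (one decimal).
#' @examples
#' gcContent("ACGT")  # 50
#' @export
gcContent <- function(seq) {
  s <- toupper(as.character(seq))
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  acgt <- sum(v %in% BASES)
  if (acgt == 0) stop("sequence has no A/C/G/T bases")
  .roundHalfUp(100 * sum(v %in% c("G", "C")) / acgt, 1)
}

# Strip subcluster digit suffixes: A1, A2, A3 -> A.
.topLevelCluster <- function(x) sub("[_ ]?[0-9]+$", "", x)

#' Summarise a phage population record table
#'
#' Computes the descriptive summary of a population table in the layout of
#' [loadPhageTable()]: per-family counts and percentages (rounded half-up to
#' integer), per-genus counts and prevalence within each family (one
#' decimal), min/max ranges of genome size, G+C and CDS count, and the
#' distinct top-level cluster labels per cluster column (subcluster digits
#' collapsed, A1 -> A).
#'
#' Rows flagged \code{suspect_typo} are excluded from the genome-size range
#' (their other fields are retained); set \code{includeSuspect = TRUE} to
#' keep them.
#'
#' @param records data.frame in the layout of [loadPhageTable()].
#' @param includeSuspect keep \code{suspect_typo} rows in the genome-size
#'   range?
#' @return A list: \code{n_genomes}, \code{family_counts},
#'   \code{family_pct}, \code{genus_within_family_pct},
#'   \code{genome_size_range}, \code{gc_range}, \code{cds_range},
#'   \code{cluster_levels} (named list per cluster column).
#' @export
summarizePopulation <- function(records, includeSuspect = FALSE) {
  if (nrow(records) < 1L) stop("need at least one record")
  n <- nrow(records)
  famCounts <- sort(table(records$family), decreasing = TRUE)
  famPct <- .roundHalfUp(100 * famCounts / n)
  genusPct <- lapply(names(famCounts), function(fam) {
    sub <- records[records$family == fam, ]
    g <- sort(table(sub$genus), decreasing = TRUE)
    .roundHalfUp(100 * g / nrow(sub), 1)
  })
  names(genusPct) <- names(famCounts)
  sizeRows <- if (includeSuspect || is.null(records$suspect_typo)) records
              else records[!records$suspect_typo, ]
  clusterCols <- grep("^cluster_", names(records), value = TRUE)
  clusterLevels <- lapply(records[clusterCols], function(x)
    sort(unique(.topLevelCluster(x))))
  list(
    n_genomes = n,
    family_counts = famCounts,
    family_pct = famPct,
    genus_within_family_pct = genusPct,
    genome_size_range = range(sizeRows$genome_size),
    gc_range = range(records$gc),
    cds_range = range(records$n_cds),
    cluster_levels = clusterLevels)
}
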