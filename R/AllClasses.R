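#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement width
#' @importFrom GenomicRanges GRanges start end strand seqnames
#' @importFrom IRanges IRanges
NULL

#' Simulation configuration for synthetic phage populations
#'
#' Holds all parameters of the mosaic phage population simulator: population
#' structure (clusters, genomes per cluster), genome geometry (length and G+C
#' ranges, module and gene counts), divergence rates (substitutions per site
#' within and between clusters), and per-genome probabilities of the mosaic
#' events the simulator can apply (horizontal module swaps, inversions, module
#' loss, tandem repeat regions).
#'
#' Defaults emulate a population of tailed dsDNA coliphages: genomes of
#' 44,324--173,384 bp with G+C between 35.5 and 46.4%, organised in three
#' clusters whose members diverge by about 0.01 substitutions/site while the
#' cluster ancestors sit 0.15 substitutions/site from their common root.
#'
#' @slot nClusters integer, number of true clusters.
#' @slot genomesPerCluster integer, genomes per cluster.
#' @slot genomeLengthRange numeric length-2, admissible genome length (bp).
#' @slot gcRange numeric length-2, admissible G+C fraction.
#' @slot nCoreModules integer, number of conserved modules (the first is
#'   always the DNA-packaging module, the second the exonuclease module).
#' @slot nVariableModules integer, minimum number of variable modules; more
#'   are appended until the target genome length is reached.
#' @slot genesPerModule integer length-2, genes per non-fixed module.
#' @slot withinClusterSubRate numeric, substitutions/site from cluster
#'   ancestor to each genome.
#' @slot betweenClusterSubRate numeric, substitutions/site from root to each
#'   cluster ancestor; must exceed \code{withinClusterSubRate}.
#' @slot hgtSwapProb numeric, per-genome probability of a horizontal module
#'   swap from another cluster.
#' @slot inversionProb numeric, per-genome probability of a module inversion.
#' @slot moduleLossProb numeric, per-variable-module probability of loss.
#' @slot repeatRegionProb numeric, per-genome probability of a tandem repeat
#'   region (duplication of one variable module).
#' @slot seed integer, RNG seed; all randomness flows from it.
#'
#' @seealso [simConfig()], [generatePopulation()]
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    nClusters = "integer",
    genomesPerCluster = "integer",
    genomeLengthRange = "numeric",
    gcRange = "numeric",
    nCoreModules = "integer",
    nVariableModules = "integer",
    genesPerModule = "integer",
    withinClusterSubRate = "numeric",
    betweenClusterSubRate = "numeric",
    hgtSwapProb = "numeric",
    inversionProb = "numeric",
    moduleLossProb = "numeric",
    repeatRegionProb = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character(0)
  chkProb <- function(x, name) {
    if (length(x) != 1 || is.na(x) || x < 0 || x > 1)
      sprintf("'%s' must be a single value in [0, 1]", name)
    else character(0)
  }
  if (object@nClusters < 1L) msg <- c(msg, "'nClusters' must be >= 1")
  if (object@genomesPerCluster < 1L)
    msg <- c(msg, "'genomesPerCluster' must be >= 1")
  if (length(object@genomeLengthRange) != 2 ||
      any(object@genomeLengthRange < 20000) ||
      any(object@genomeLengthRange > 200000) ||
      diff(object@genomeLengthRange) < 0)
    msg <- c(msg, "'genomeLengthRange' must be an increasing interval within [20000, 200000]")
  if (length(object@gcRange) != 2 || any(object@gcRange <= 0) ||
      any(object@gcRange >= 1) || diff(object@gcRange) < 0)
    msg <- c(msg, "'gcRange' must be an increasing interval within (0, 1)")
  if (object@nCoreModules < 2L)
    msg <- c(msg, "'nCoreModules' must be >= 2 (packaging + nuclease modules)")
  if (object@nVariableModules < 1L)
    msg <- c(msg, "'nVariableModules' must be >= 1")
  if (length(object@genesPerModule) != 2 || object@genesPerModule[1] < 1L ||
      diff(object@genesPerModule) < 0)
    msg <- c(msg, "'genesPerModule' must be an increasing positive integer range")
  msg <- c(msg,
    chkProb(object@withinClusterSubRate, "withinClusterSubRate"),
    chkProb(object@betweenClusterSubRate, "betweenClusterSubRate"),
    chkProb(object@hgtSwapProb, "hgtSwapProb"),
    chkProb(object@inversionProb, "inversionProb"),
    chkProb(object@moduleLossProb, "moduleLossProb"),
    chkProb(object@repeatRegionProb, "repeatRegionProb"))
  if (length(msg) == 0 && object@nClusters > 1L &&
      object@betweenClusterSubRate <= object@withinClusterSubRate)
    msg <- c(msg, "'betweenClusterSubRate' must exceed 'withinClusterSubRate'")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' @param nClusters number of true clusters.
#' @param genomesPerCluster genomes per cluster.
#' @param genomeLengthRange admissible genome length interval (bp), within
#'   \[20000, 200000\].
#' @param gcRange admissible G+C fraction interval.
#' @param nCoreModules number of conserved modules (>= 2).
#' @param nVariableModules minimum number of variable modules.
#' @param genesPerModule integer range of genes per module.
#' @param withinClusterSubRate substitutions/site within clusters.
#' @param betweenClusterSubRate substitutions/site between root and cluster
#'   ancestors; must exceed the within-cluster rate.
#' @param hgtSwapProb per-genome probability of a horizontal module swap.
#' @param inversionProb per-genome probability of a module inversion.
#' @param moduleLossProb per-variable-module probability of module loss.
#' @param repeatRegionProb per-genome probability of a tandem repeat region.
#' @param seed integer RNG seed.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nClusters = 2, genomesPerCluster = 3,
#'                  genomeLengthRange = c(40000, 50000), seed = 42)
#' @export
simConfig <- function(nClusters = 3L,
                      genomesPerCluster = 5L,
                      genomeLengthRange = c(44324, 173384),
                      gcRange = c(0.355, 0.464),
                      nCoreModules = 5L,
                      nVariableModules = 4L,
                      genesPerModule = c(4L, 8L),
                      withinClusterSubRate = 0.01,
                      betweenClusterSubRate = 0.15,
                      hgtSwapProb = 0,
                      inversionProb = 0,
                      moduleLossProb = 0,
                      repeatRegionProb = 0,
                      seed = 1L) {
  obj <- new("SimConfig",
    nClusters = as.integer(nClusters),
    genomesPerCluster = as.integer(genomesPerCluster),
    genomeLengthRange = as.numeric(genomeLengthRange),
    gcRange = as.numeric(gcRange),
    nCoreModules = as.integer(nCoreModules),
    nVariableModules = as.integer(nVariableModules),
    genesPerModule = as.integer(genesPerModule),
    withinClusterSubRate = as.numeric(withinClusterSubRate),
    betweenClusterSubRate = as.numeric(betweenClusterSubRate),
    hgtSwapProb = as.numeric(hgtSwapProb),
    inversionProb = as.numeric(inversionProb),
    moduleLossProb = as.numeric(moduleLossProb),
    repeatRegionProb = as.numeric(repeatRegionProb),
    seed = as.integer(seed))
  validObject(obj)
  obj
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nClusters, "cluster(s) x",
      object@genomesPerCluster, "genome(s)\n")
  cat("  length range:", paste(object@genomeLengthRange, collapse = "-"),
      "bp; G+C range:", paste(object@gcRange, collapse = "-"), "\n")
  cat("  divergence (subs/site): within", object@withinClusterSubRate,
      "/ between", object@betweenClusterSubRate, "\n")
  cat("  event probs: hgt", object@hgtSwapProb, "inv", object@inversionProb,
      "loss", object@moduleLossProb, "repeat", object@repeatRegionProb,
      "; seed", object@seed, "\n")
})

#' Synthetic phage population with recorded ground truth
#'
#' Container for a simulated population: genome sequences, gene annotations,
#' and the ground truth the simulator recorded while generating them (true
#' cluster labels, true gene families, module layout per genome and applied
#' rearrangement events). The truth slots let every downstream analysis stage
#' be validated against known answers.
#'
#' @slot genomes [Biostrings::DNAStringSet] of genome sequences, named by
#'   genome id.
#' @slot genes [GenomicRanges::GRanges] of gene features (seqnames = genome
#'   ids; 1-based inclusive coordinates) with metadata columns \code{gene_id},
#'   \code{product}, \code{family_id} (true ortholog family) and
#'   \code{module_id}.
#' @slot clusters named character, genome id -> true cluster label.
#' @slot modules data.frame with one row per module occurrence per genome:
#'   \code{genome_id}, \code{module_id}, \code{position} (rank along the
#'   genome), \code{orientation} (+1/-1).
#' @slot events data.frame of applied rearrangements: \code{genome_id},
#'   \code{event} (hgt_swap/inversion/loss/repeat), \code{module_id},
#'   \code{donor}.
#' @slot gcTargets named numeric, genome id -> target G+C fraction.
#' @slot elements list with components \code{clusters} (per-cluster ancestral
#'   element tables, the donor source for horizontal swaps) and \code{genomes}
#'   (per-genome element tables); internal bookkeeping for
#'   [applyRearrangement()].
#' @slot config the [SimConfig-class] used.
#' @exportClass PhagePopulation
setClass("PhagePopulation",
  representation(
    genomes = "DNAStringSet",
    genes = "GRanges",
    clusters = "character",
    modules = "data.frame",
    events = "data.frame",
    gcTargets = "numeric",
    elements = "list",
    config = "SimConfig"
  )
)

setValidity("PhagePopulation", function(object) {
  msg <- character(0)
  ids <- names(object@genomes)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "genome ids must be unique and non-empty")
  if (!all(names(object@clusters) %in% ids) ||
      !all(ids %in% names(object@clusters)))
    msg <- c(msg, "every genome must have exactly one true cluster label")
  g <- object@genes
  if (length(g)) {
    if (anyDuplicated(mcols(g)$gene_id))
      msg <- c(msg, "gene ids must be unique")
    w <- width(object@genomes)[match(as.character(seqnames(g)), ids)]
    if (any(start(g) < 1) || any(end(g) > w))
      msg <- c(msg, "gene coordinates must lie within their genome")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PhagePopulation", function(object) {
  cat("PhagePopulation:", length(object@genomes), "genomes,",
      length(object@genes), "genes,",
      length(unique(object@clusters)), "true cluster(s)\n")
  cat("  lengths:", paste(range(width(object@genomes)), collapse = "-"),
      "bp;", nrow(object@events), "recorded event(s)\n")
})
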