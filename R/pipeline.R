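# End-to-end orchestration: population -> distances -> clusters -> marker
# trees -> agreement -> pan genome -> LCBs -> taxonomy -> report.

#' Pairwise adjusted-Rand concordance matrix of cluster assignments
#'
#' @param assignments named list of named cluster-label vectors over the same
#'   genome set (e.g. from [cutDendrogram()]).
#' @return Symmetric numeric matrix of adjusted Rand indices, unit diagonal.
#' @export
concordance <- function(assignments) {
  if (length(assignments) < 1L) stop("need at least one assignment")
  ids <- names(assignments[[1]])
  for (a in assignments) {
    if (!setequal(names(a), ids))
      stop("all assignments must cover the same genome set")
  }
  n <- length(assignments)
  nm <- names(assignments)
  if (is.null(nm)) nm <- paste0("assignment", seq_len(n))
  m <- matrix(1, n, n, dimnames = list(nm, nm))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        m[i, j] <- m[j, i] <-
          adjustedRandIndex(assignments[[i]][ids], assignments[[j]][ids])
      }
    }
  }
  m
}

#' Run the full diversity-analysis pipeline
#'
#' Executes, in dependency order: population simulation (or use of a supplied
#' population), canonical k-mer distance matrices and UPGMA cut-height
#' cluster calls for each k, gene-family clustering with gene-content
#' distances and cluster calls, per-cluster pan-genome partitions,
#' marker-gene alignments with TN93 + NJ trees and bootstrap supports plus
#' marker-based cluster calls, a pairwise adjusted-Rand concordance matrix
#' over all cluster assignments, gene-order LCB detection, and ICTV-style
#' genus assignment against one reference per true cluster. Reruns with the
#' same inputs and seed are bit-identical.
#'
#' @param population a [PhagePopulation-class], or a [SimConfig-class] to
#'   simulate one.
#' @param kValues k-mer lengths (default \code{c(10, 21)}).
#' @param kmerCutHeight cut height for k-mer dendrograms (default 0.82).
#' @param geneCutHeight cut height for the gene-content dendrogram (default
#'   0.81).
#' @param markerCutHeight cut height (substitutions/site) for marker-based
#'   cluster calls (default 0.2).
#' @param identityThreshold gene-family identity threshold (default 0.90).
#' @param markers marker product names; empty vector skips the marker and
#'   concordance-with-marker stages.
#' @param bootstrapReplicates bootstrap replicates per marker (default 1000).
#' @param seed integer seed driving every stochastic stage.
#' @param outputDir optional directory; when given, all stage outputs are
#'   written (FASTA/GFF3/PHYLIP/Newick/TSV and a plain-text report) and an
#'   md5 manifest is included in the result.
#' @return A run-report list with per-stage results: \code{population},
#'   \code{distances}, \code{dendrograms}, \code{assignments},
#'   \code{concordance}, \code{families}, \code{panGenome},
#'   \code{markerTrees}, \code{lcbs}, \code{taxonomy}, \code{skipped},
#'   \code{manifest}.
#' @export
runPipeline <- function(population = simConfig(),
                        kValues = c(10L, 21L),
                        kmerCutHeight = 0.82,
                        geneCutHeight = 0.81,
                        markerCutHeight = 0.2,
                        identityThreshold = 0.90,
                        markers = c("terminase large subunit",
                                    "portal protein", "exonuclease"),
                        bootstrapReplicates = 1000L,
                        seed = 1L,
                        outputDir = NULL) {
  if (any(c(kmerCutHeight, geneCutHeight, markerCutHeight) < 0))
    stop("cut heights must be >= 0")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  pop <- stage("population", {
    if (is(population, "SimConfig")) generatePopulation(population)
    else if (is(population, "PhagePopulation")) population
    else stop("'population' must be a SimConfig or PhagePopulation")
  })
  set.seed(seed)
  gens <- genomes(pop)
  ids <- names(gens)
  skipped <- character(0)

  distances <- list(); dendrograms <- list(); assignments <- list()
  for (k in kValues) {
    nm <- paste0("kmer", k)
    distances[[nm]] <- stage(nm, kmerDistanceMatrix(gens, k = k))
    dendrograms[[nm]] <- upgma(distances[[nm]])
    assignments[[nm]] <- cutDendrogram(dendrograms[[nm]], kmerCutHeight)
  }

  famTable <- stage("gene_content", {
    geneSeqs <- extractGeneSequences(gens, pop@genes)
    clusterGeneFamilies(geneSeqs, as.character(seqnames(pop@genes)),
                        identityThreshold = identityThreshold)
  })
  pa <- presenceAbsenceMatrix(famTable, genomeIds = ids)
  distances$gene_content <- stage("gene_content", geneContentDistance(pa))
  dendrograms$gene_content <- upgma(distances$gene_content)
  assignments$gene_content <- cutDendrogram(dendrograms$gene_content,
                                            geneCutHeight)

  panGenome <- stage("pan_genome", {
    wgs <- assignments[[paste0("kmer", kValues[1])]]
    rows <- lapply(sort(unique(wgs)), function(cl) {
      members <- names(wgs)[wgs == cl]
      if (length(members) < 2L) return(NULL)
      cbind(cluster = cl,
            partitionPanGenome(pa[members, colSums(pa[members, , drop = FALSE]) > 0,
                                  drop = FALSE]))
    })
    do.call(rbind, rows)
  })

  markerTrees <- list()
  if (length(markers)) {
    for (mk in markers) {
      nm <- gsub(" ", "_", mk)
      res <- stage(paste0("marker:", mk), {
        seqs <- markerSequences(pop, mk)
        aln <- progressiveAlign(seqs)
        dmat <- tn93DistanceMatrix(aln)
        tree <- bootstrapSupport(aln, nReplicates = bootstrapReplicates,
                                 seed = seed + match(mk, markers))
        # per-genome cluster call: first copy per genome, ultrametric cut
        firstCopy <- !duplicated(sub("__copy[0-9]+$", "", names(aln)))
        dGen <- stats::as.dist(as.matrix(dmat)[firstCopy, firstCopy])
        attr(dGen, "Labels") <- sub("__copy[0-9]+$", "",
                                    names(aln)[firstCopy])
        asg <- cutDendrogram(upgma(dGen), markerCutHeight)
        list(alignment = aln, distances = dmat, tree = tree,
             assignment = asg[ids])
      })
      markerTrees[[nm]] <- res
      a <- res$assignment
      attr(a, "cut_height") <- markerCutHeight
      assignments[[nm]] <- a
    }
  } else {
    skipped <- c(skipped, "markers", "marker_concordance")
  }

  conc <- stage("concordance", concordance(assignments))

  lcbs <- stage("lcbs", {
    annot <- pop@genes
    mcols(annot)$family_id <- famTable$family_id[
      match(mcols(annot)$gene_id, famTable$gene_id)]
    findLcbs(annot)
  })

  taxonomy <- stage("taxonomy", {
    truth <- trueClusters(pop)
    refs <- ids[!duplicated(truth)]
    refTaxa <- data.frame(genome_id = refs,
                          genus = paste0("Genus_", truth[refs]),
                          stringsAsFactors = FALSE)
    calls <- assignGenus(gens, gens[refs], refTaxa)
    calls$true_cluster <- truth[calls$genome_id]
    calls
  })

  report <- list(
    population = pop,
    parameters = list(kValues = kValues, kmerCutHeight = kmerCutHeight,
                      geneCutHeight = geneCutHeight,
                      markerCutHeight = markerCutHeight,
                      identityThreshold = identityThreshold,
                      markers = markers,
                      bootstrapReplicates = bootstrapReplicates,
                      seed = seed),
    distances = distances,
    dendrograms = dendrograms,
    assignments = assignments,
    concordance = conc,
    families = famTable,
    presenceAbsence = pa,
    panGenome = panGenome,
    markerTrees = markerTrees,
    lcbs = lcbs,
    taxonomy = taxonomy,
    skipped = skipped,
    manifest = NULL)

  if (!is.null(outputDir)) {
    report$manifest <- .writeRunOutputs(report, outputDir)
  }
  report
}

.writeRunOutputs <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pop <- report$population
  writePopulation(pop, dir)
  for (nm in names(report$distances))
    writePhylipDist(report$distances[[nm]],
                    file.path(dir, paste0("dist_", nm, ".phylip")))
  for (nm in names(report$dendrograms))
    writeNewick(dendrogramToPhylo(report$dendrograms[[nm]]),
                file.path(dir, paste0("dendrogram_", nm, ".nwk")))
  for (nm in names(report$markerTrees))
    writeNewick(report$markerTrees[[nm]]$tree,
                file.path(dir, paste0("marker_", nm, ".nwk")))
  asg <- do.call(rbind, lapply(names(report$assignments), function(nm)
    data.frame(method = nm, genome_id = names(report$assignments[[nm]]),
               cluster = unname(report$assignments[[nm]]))))
  utils::write.table(asg, file.path(dir, "assignments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$families, file.path(dir, "gene_families.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$presenceAbsence,
                     file.path(dir, "presence_absence.tsv"),
                     sep = "\t", quote = FALSE)
  if (!is.null(report$panGenome))
    utils::write.table(report$panGenome, file.path(dir, "pan_genome.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$lcbs$blocks, file.path(dir, "lcb_blocks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$lcbs$occurrences,
                     file.path(dir, "lcb_occurrences.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$taxonomy, file.path(dir, "taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(round(report$concordance, 6),
                     file.path(dir, "concordance_ari.tsv"),
                     sep = "\t", quote = FALSE)
  summaryLines <- c(
    "phagepop run report",
    sprintf("genomes: %d; genes: %d", length(genomes(pop)),
            length(geneAnnotations(pop))),
    sprintf("assignments: %s", paste(names(report$assignments),
                                     collapse = ", ")),
    sprintf("skipped stages: %s",
            if (length(report$skipped)) paste(report$skipped, collapse = ", ")
            else "none"),
    sprintf("seed: %d", report$parameters$seed))
  writeLines(summaryLines, file.path(dir, "report.txt"))
  files <- sort(list.files(dir, full.names = TRUE))
  data.frame(file = basename(files),
             md5 = unname(tools::md5sum(files)),
             stringsAsFactors = FALSE)
}
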