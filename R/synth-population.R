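# Mosaic phage population simulator.
#
# Genomes are linear element sequences: modules (runs of genes separated by
# short intra-module spacers) separated by inter-module spacers. The first
# module is always the conserved DNA-packaging module (terminase small
# subunit, terminase large subunit, portal protein, major capsid protein,
# scaffold protein, in that order, all on the plus strand); the second is the
# nuclease module carrying 1-3 exonuclease paralogs (the per-cluster copy
# number emulates the observed cluster-associated variation). A single root
# genome is mutated into cluster ancestors (uniform substitutions at the
# between-cluster rate, then a G+C tuning pass toward the cluster's target),
# and each genome is the cluster ancestor mutated at the within-cluster rate.
# Mosaic events (horizontal module swaps, inversions, module loss, tandem
# repeats) are applied per genome afterwards and recorded as ground truth.

# Fixed widths of the packaging-module genes (bp, multiples of 3).
.PACKAGING <- data.frame(
  product = c("terminase small subunit", "terminase large subunit",
              "portal protein", "major capsid protein", "scaffold protein"),
  width = c(546L, 1602L, 1500L, 1041L, 702L),
  stringsAsFactors = FALSE)
.EXO_WIDTH <- 903L

# Gene length distribution: 300 + 3*Geom-ish tail, capped at 3000 bp.
.drawGeneWidths <- function(n) {
  300L + 3L * pmin(floor(stats::rexp(n, rate = 1 / 83)), 900L)
}

.drawSpacerWidths <- function(n) sample(2:200, n, replace = TRUE)

# Random sequence at a given G+C fraction.
.randomSeq <- function(width, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, width, replace = TRUE, prob = p), collapse = "")
}

# Root element table: one row per spacer/gene, genome order.
# Columns: kind, module_id, module_type, occ, gene_index, family_id, product,
# strand, orientation, width.
.buildRootLayout <- function(config) {
  lenRange <- config@genomeLengthRange
  target <- stats::runif(1, lenRange[1], lenRange[2])
  rows <- list()
  famCounter <- 0L
  addModule <- function(moduleId, type, products, strands, widths) {
    n <- length(products)
    fams <- sprintf("fam%03d", famCounter + seq_len(n))
    famCounter <<- famCounter + n
    intra <- .drawSpacerWidths(n - 1L)
    out <- vector("list", 2L * n)
    out[[1]] <- data.frame(kind = "spacer", module_id = NA_character_,
      module_type = NA_character_, occ = 1L, gene_index = NA_integer_,
      family_id = NA_character_, product = NA_character_,
      strand = NA_character_, orientation = NA_integer_,
      width = .drawSpacerWidths(1L), stringsAsFactors = FALSE)
    k <- 1L
    for (i in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- data.frame(kind = "gene", module_id = moduleId,
        module_type = type, occ = 1L, gene_index = i, family_id = fams[i],
        product = products[i], strand = strands[i], orientation = 1L,
        width = widths[i], stringsAsFactors = FALSE)
      if (i < n) {
        k <- k + 1L
        out[[k]] <- data.frame(kind = "spacer", module_id = moduleId,
          module_type = type, occ = 1L, gene_index = NA_integer_,
          family_id = NA_character_, product = NA_character_,
          strand = NA_character_, orientation = NA_integer_,
          width = intra[i], stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out[seq_len(k)])
  }
  hypModule <- function(moduleId, type) {
    nGenes <- sample(seq(config@genesPerModule[1], config@genesPerModule[2]), 1L)
    addModule(moduleId, type,
      products = rep("hypothetical protein", nGenes),
      strands = sample(c("+", "-"), nGenes, replace = TRUE),
      widths = .drawGeneWidths(nGenes))
  }
  mCount <- 0L
  nextId <- function() { mCount <<- mCount + 1L; sprintf("M%02d", mCount) }
  rows[[1]] <- addModule(nextId(), "core", .PACKAGING$product,
                         rep("+", nrow(.PACKAGING)), .PACKAGING$width)
  rows[[2]] <- addModule(nextId(), "core", rep("exonuclease", 3L),
                         rep("+", 3L), rep(.EXO_WIDTH, 3L))
  for (i in seq_len(config@nCoreModules - 2L))
    rows[[length(rows) + 1L]] <- hypModule(nextId(), "core")
  nVar <- 0L
  repeat {
    total <- sum(vapply(rows, function(r) sum(r$width), numeric(1)))
    if (nVar >= config@nVariableModules && total >= target) break
    cand <- hypModule(nextId(), "variable")
    if (total + sum(cand$width) > lenRange[2]) {
      # trim genes off the tail module so the genome stays within range
      keep <- which(cumsum(cand$width) <= lenRange[2] - total)
      if (length(keep) < 2L) { mCount <- mCount - 1L; break }
      if (cand$kind[max(keep)] == "spacer") keep <- keep[-length(keep)]
      cand <- cand[keep, , drop = FALSE]
    }
    rows[[length(rows) + 1L]] <- cand
    nVar <- nVar + 1L
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Concatenate element seqs, apply f to the full string, split back by widths.
.onConcat <- function(els, f) {
  full <- f(paste(els$seq, collapse = ""))
  ends <- cumsum(els$width)
  els$seq <- substring(full, ends - els$width + 1L, ends)
  els
}

# Targeted A/T <-> G/C substitutions moving realized G+C to `target`.
.gcTune <- function(s, target) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  isGC <- v %in% c("G", "C")
  delta <- round((target - mean(isGC)) * length(v))
  if (delta > 0) {
    idx <- sample(which(!isGC), delta)
    v[idx] <- sample(c("G", "C"), delta, replace = TRUE)
  } else if (delta < 0) {
    idx <- sample(which(isGC), -delta)
    v[idx] <- sample(c("A", "T"), -delta, replace = TRUE)
  }
  paste(v, collapse = "")
}

#' Mutate a DNA sequence at a fixed per-site substitution rate
#'
#' Each site is substituted independently with probability \code{rate}; the
#' replacement base is drawn uniformly from the three alternatives, so a
#' substituted site never retains its original base. Length is preserved (no
#' indels).
#'
#' @param seq a single ACGT character string.
#' @param rate substitution probability per site, in \[0, 1\].
#' @param seed optional integer; if given, seeds the RNG first.
#' @return The mutated sequence (character scalar of the same length).
#' @examples
#' mutateSequence("ACGTACGT", 0, seed = 1)   # unchanged
#' @export
mutateSequence <- function(seq, rate, seed = NULL) {
  if (!is.character(seq) || length(seq) != 1L)
    stop("'seq' must be a single character string")
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) ||
      rate < 0 || rate > 1)
    stop("'rate' must be a single value in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!(v %in% BASES))
  if (length(bad))
    stop("non-ACGT base '", v[bad[1]], "' at position ", bad[1])
  idx <- which(stats::runif(length(v)) < rate)
  if (length(idx)) {
    off <- sample.int(3L, length(idx), replace = TRUE)
    v[idx] <- BASES[((match(v[idx], BASES) - 1L + off) %% 4L) + 1L]
  }
  paste(v, collapse = "")
}

# --- element-table editing (shared by the generator and applyRearrangement) --

.moduleRows <- function(els, moduleId, occ = NULL) {
  rows <- which(!is.na(els$module_id) & els$module_id == moduleId &
                  (if (is.null(occ)) TRUE else els$occ == occ))
  if (!length(rows))
    stop("unknown module '", moduleId, "' in this genome")
  if (any(diff(rows) != 1L))
    stop("module '", moduleId, "' is not contiguous (multiple copies?); ",
         "pass 'occ' to select one copy")
  rows
}

.eventInvert <- function(els, moduleId, occ = 1L) {
  rows <- .moduleRows(els, moduleId, occ)
  sub <- els[rev(rows), , drop = FALSE]
  sub$seq <- vapply(sub$seq, .revcomp, character(1), USE.NAMES = FALSE)
  isG <- sub$kind == "gene"
  sub$strand[isG] <- ifelse(sub$strand[isG] == "+", "-", "+")
  sub$orientation[isG] <- -sub$orientation[isG]
  els[rows, ] <- sub
  els
}

.eventLoss <- function(els, moduleId, occ = 1L) {
  rows <- .moduleRows(els, moduleId, occ)
  els[-rows, , drop = FALSE]
}

.eventRepeat <- function(els, moduleId) {
  rows <- .moduleRows(els, moduleId)
  dup <- els[rows, , drop = FALSE]
  dup$occ <- dup$occ + 1L
  isG <- dup$kind == "gene"
  dup$gene_id[isG] <- paste0(dup$gene_id[isG], "r2")
  # separate the two copies by a short spacer carrying the module id
  sep <- dup[1L, , drop = FALSE]
  sep$kind <- "spacer"; sep$gene_index <- NA_integer_
  sep$family_id <- NA_character_; sep$product <- NA_character_
  sep$strand <- NA_character_; sep$orientation <- NA_integer_
  sep$gene_id <- NA_character_
  sep$width <- 10L
  sep$seq <- .randomSeq(10L, 0.5)
  rbind(els[seq_len(max(rows)), , drop = FALSE], sep, dup,
        if (max(rows) < nrow(els))
          els[(max(rows) + 1L):nrow(els), , drop = FALSE])
}

.eventHgtSwap <- function(els, moduleId, donorEls, occ = 1L) {
  rows <- .moduleRows(els, moduleId, occ)
  drows <- which(!is.na(donorEls$module_id) & donorEls$module_id == moduleId)
  if (!length(drows)) stop("donor cluster lacks module '", moduleId, "'")
  if (length(drows) != length(rows) ||
      any(donorEls$kind[drows] != els$kind[rows]) ||
      any(donorEls$width[drows] != els$width[rows]))
    stop("module '", moduleId, "' layout differs between donor and recipient")
  els$seq[rows] <- donorEls$seq[drows]
  els
}

# Rebuild genome string + per-gene coordinate table from an element table.
.realizeGenome <- function(els, genomeId) {
  ends <- cumsum(els$width)
  starts <- ends - els$width + 1L
  isG <- els$kind == "gene"
  list(
    seq = paste(els$seq, collapse = ""),
    genes = data.frame(
      genome_id = genomeId,
      gene_id = els$gene_id[isG],
      start = starts[isG], end = ends[isG],
      strand = els$strand[isG],
      product = els$product[isG],
      family_id = els$family_id[isG],
      module_id = els$module_id[isG],
      stringsAsFactors = FALSE))
}

# Ordered module occurrences of one genome.
.moduleOccurrences <- function(els, genomeId) {
  isG <- els$kind == "gene"
  key <- paste(els$module_id[isG], els$occ[isG])
  first <- !duplicated(key)
  data.frame(
    genome_id = genomeId,
    module_id = els$module_id[isG][first],
    occ = els$occ[isG][first],
    position = seq_len(sum(first)),
    orientation = els$orientation[isG][first],
    stringsAsFactors = FALSE)
}

.assemblePopulation <- function(genomeEls, clusters, clusterEls, config,
                                events, gcTargets) {
  realized <- lapply(names(genomeEls),
                     function(g) .realizeGenome(genomeEls[[g]], g))
  names(realized) <- names(genomeEls)
  seqs <- Biostrings::DNAStringSet(vapply(realized, `[[`, character(1), "seq"))
  names(seqs) <- names(genomeEls)
  genesDf <- do.call(rbind, lapply(realized, `[[`, "genes"))
  gr <- GenomicRanges::GRanges(
    seqnames = genesDf$genome_id,
    ranges = IRanges::IRanges(start = genesDf$start, end = genesDf$end),
    strand = genesDf$strand)
  mcols(gr)$gene_id <- genesDf$gene_id
  mcols(gr)$product <- genesDf$product
  mcols(gr)$family_id <- genesDf$family_id
  mcols(gr)$module_id <- genesDf$module_id
  mods <- do.call(rbind, lapply(names(genomeEls),
                                function(g) .moduleOccurrences(genomeEls[[g]], g)))
  rownames(mods) <- NULL
  new("PhagePopulation", genomes = seqs, genes = gr, clusters = clusters,
      modules = mods, events = events, gcTargets = gcTargets,
      elements = list(clusters = clusterEls, genomes = genomeEls),
      config = config)
}

#' Generate a synthetic phage population with recorded ground truth
#'
#' Builds a clustered, mosaic population of linear dsDNA phage genomes from a
#' single simulated root: cluster ancestors diverge from the root at
#' \code{betweenClusterSubRate} (with a G+C tuning pass toward a per-cluster
#' target drawn from \code{gcRange}), genomes diverge from their cluster
#' ancestor at \code{withinClusterSubRate}, and mosaic events (horizontal
#' module swaps, inversions, module losses, tandem repeat regions) are applied
#' per genome at the configured probabilities. Every genome carries the
#' conserved DNA-packaging module (terminase small subunit, terminase large
#' subunit, portal protein, capsid, scaffold, in that order) and 1--3
#' exonuclease genes (copy number fixed per cluster).
#'
#' The run is fully deterministic for a fixed \code{config@seed}: randomness
#' flows from one generator in a fixed call order (root layout, cluster G+C
#' targets, exonuclease copy numbers, cluster ancestors in cluster order,
#' genomes in genome order, then events per genome in the order swap,
#' inversion, loss, repeat).
#'
#' @param config a [SimConfig-class].
#' @return A [PhagePopulation-class] with genomes, gene annotations and truth.
#' @examples
#' pop <- generatePopulation(simConfig(nClusters = 2, genomesPerCluster = 2,
#'   genomeLengthRange = c(20000, 24000), nVariableModules = 1, seed = 7))
#' pop
#' @export
generatePopulation <- function(config) {
  if (!is(config, "SimConfig")) stop("'config' must be a SimConfig")
  validObject(config)
  set.seed(config@seed)
  rootGc <- mean(config@gcRange)
  layout <- .buildRootLayout(config)
  layout$seq <- NA_character_
  for (i in seq_len(nrow(layout)))
    layout$seq[i] <- .randomSeq(layout$width[i], rootGc)
  # exonuclease paralogs: diverged copies of the first, so each copy is its
  # own family both in truth and at a 90% identity threshold
  exoRows <- which(!is.na(layout$product) & layout$product == "exonuclease")
  for (i in exoRows[-1])
    layout$seq[i] <- mutateSequence(layout$seq[exoRows[1]], 0.25)

  clusterLabels <- paste0("C", seq_len(config@nClusters))
  gcTargets <- stats::runif(config@nClusters, config@gcRange[1],
                            config@gcRange[2])
  names(gcTargets) <- clusterLabels
  nExo <- sample(1:3, config@nClusters, replace = TRUE)

  clusterEls <- list()
  for (ci in seq_len(config@nClusters)) {
    els <- layout
    if (nExo[ci] < 3L) {
      dropG <- exoRows[(nExo[ci] + 1L):3L]
      # drop the paralog genes and their preceding intra-module spacers
      dropS <- dropG - 1L
      dropS <- dropS[els$kind[dropS] == "spacer" &
                       !is.na(els$module_id[dropS])]
      els <- els[-c(dropG, dropS), , drop = FALSE]
    }
    if (config@nClusters > 1L)
      els <- .onConcat(els, function(s)
        mutateSequence(s, config@betweenClusterSubRate))
    els <- .onConcat(els, function(s) .gcTune(s, gcTargets[ci]))
    clusterEls[[clusterLabels[ci]]] <- els
  }

  genomeEls <- list()
  clusters <- character(0)
  genomeGc <- numeric(0)
  gi <- 0L
  for (ci in seq_len(config@nClusters)) {
    for (gj in seq_len(config@genomesPerCluster)) {
      gi <- gi + 1L
      gid <- sprintf("phage_%02d", gi)
      els <- clusterEls[[clusterLabels[ci]]]
      if (config@withinClusterSubRate > 0)
        els <- .onConcat(els, function(s)
          mutateSequence(s, config@withinClusterSubRate))
      els$gene_id <- NA_character_
      isG <- els$kind == "gene"
      els$gene_id[isG] <- sprintf("%s_g%03d", gid, seq_len(sum(isG)))
      genomeEls[[gid]] <- els
      clusters[gid] <- clusterLabels[ci]
      genomeGc[gid] <- gcTargets[ci]
    }
  }

  events <- data.frame(genome_id = character(0), event = character(0),
                       module_id = character(0), donor = character(0),
                       stringsAsFactors = FALSE)
  varModules <- unique(layout$module_id[!is.na(layout$module_type) &
                                          layout$module_type == "variable"])
  for (gid in names(genomeEls)) {
    present <- function() intersect(varModules,
                                    unique(genomeEls[[gid]]$module_id))
    if (length(varModules) && config@nClusters > 1L &&
        stats::runif(1) < config@hgtSwapProb) {
      m <- sample(present(), 1L)
      donor <- sample(setdiff(clusterLabels, clusters[gid]), 1L)
      genomeEls[[gid]] <- .eventHgtSwap(genomeEls[[gid]], m,
                                        clusterEls[[donor]])
      events[nrow(events) + 1L, ] <- c(gid, "hgt_swap", m, donor)
    }
    if (length(varModules) && stats::runif(1) < config@inversionProb) {
      m <- sample(present(), 1L)
      genomeEls[[gid]] <- .eventInvert(genomeEls[[gid]], m)
      events[nrow(events) + 1L, ] <- c(gid, "inversion", m, NA)
    }
    if (config@moduleLossProb > 0) {
      for (m in present()) {
        if (length(present()) > 1L && stats::runif(1) < config@moduleLossProb) {
          genomeEls[[gid]] <- .eventLoss(genomeEls[[gid]], m)
          events[nrow(events) + 1L, ] <- c(gid, "loss", m, NA)
        }
      }
    }
    if (length(varModules) && stats::runif(1) < config@repeatRegionProb) {
      m <- sample(present(), 1L)
      genomeEls[[gid]] <- .eventRepeat(genomeEls[[gid]], m)
      events[nrow(events) + 1L, ] <- c(gid, "repeat", m, NA)
    }
  }

  .assemblePopulation(genomeEls, clusters, clusterEls, config, events,
                      genomeGc)
}

#' Apply a single rearrangement event to one genome
#'
#' Applies one mosaic event to the named genome of a synthetic population and
#' records it in the population's event log. \code{"hgt_swap"} replaces the
#' module's sequence with the donor cluster's ancestral version (layout must
#' match); \code{"inversion"} reverse-complements the module and flips its
#' genes' strands; \code{"loss"} removes the module; \code{"repeat"} appends a
#' tandem duplicate of the module.
#'
#' @param pop a [PhagePopulation-class].
#' @param genomeId genome to edit.
#' @param event one of \code{"hgt_swap"}, \code{"inversion"}, \code{"loss"},
#'   \code{"repeat"}.
#' @param moduleId module to act on (must exist in the genome).
#' @param donorCluster donor cluster label, required for \code{"hgt_swap"}.
#' @return The updated [PhagePopulation-class].
#' @export
applyRearrangement <- function(pop, genomeId, event, moduleId,
                               donorCluster = NULL) {
  if (!is(pop, "PhagePopulation")) stop("'pop' must be a PhagePopulation")
  if (!genomeId %in% names(pop@genomes))
    stop("unknown genome '", genomeId, "'")
  event <- match.arg(event, c("hgt_swap", "inversion", "loss", "repeat"))
  els <- pop@elements$genomes[[genomeId]]
  els <- switch(event,
    hgt_swap = {
      if (is.null(donorCluster) ||
          !donorCluster %in% names(pop@elements$clusters))
        stop("'donorCluster' must name a cluster for hgt_swap")
      .eventHgtSwap(els, moduleId, pop@elements$clusters[[donorCluster]])
    },
    inversion = .eventInvert(els, moduleId),
    loss = .eventLoss(els, moduleId),
    `repeat` = .eventRepeat(els, moduleId))
  genomeEls <- pop@elements$genomes
  genomeEls[[genomeId]] <- els
  events <- pop@events
  events[nrow(events) + 1L, ] <- c(genomeId, event, moduleId,
                                   if (is.null(donorCluster)) NA
                                   else donorCluster)
  .assemblePopulation(genomeEls, pop@clusters, pop@elements$clusters,
                      pop@config, events, pop@gcTargets)
}

#' Extract marker-gene sequences from a population
#'
#' Returns the strand-corrected nucleotide sequences of a marker gene from
#' every genome. Genomes carrying several copies (exonucleases occur in 1-3
#' copies) contribute one labelled leaf per copy, named
#' \code{genomeid__copyN}; single-copy markers are named by genome id.
#'
#' @param pop a [PhagePopulation-class].
#' @param marker product name: \code{"terminase large subunit"},
#'   \code{"portal protein"}, \code{"exonuclease"}, or any product string
#'   present in the annotation.
#' @return A named [Biostrings::DNAStringSet].
#' @export
markerSequences <- function(pop, marker = "terminase large subunit") {
  g <- pop@genes[mcols(pop@genes)$product == marker]
  if (!length(g)) stop("no genes with product '", marker, "'")
  seqs <- extractGeneSequences(pop@genomes, g)
  gid <- as.character(seqnames(g))
  copies <- stats::ave(seq_along(gid), gid, FUN = seq_along)
  multi <- gid %in% gid[duplicated(gid)]
  names(seqs) <- ifelse(multi, paste0(gid, "__copy", copies), gid)
  seqs
}
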