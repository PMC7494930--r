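# Simulator: configuration validation, mutation model, structural guarantees
# and recorded ground truth.

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(simConfig(withinClusterSubRate = 1.5), "withinClusterSubRate")
  expect_error(simConfig(genomeLengthRange = c(1000, 5000)),
               "genomeLengthRange")
  expect_error(simConfig(withinClusterSubRate = 0.2,
                         betweenClusterSubRate = 0.1),
               "betweenClusterSubRate")
  expect_error(simConfig(hgtSwapProb = -0.1), "hgtSwapProb")
})

test_that("mutateSequence preserves length and hits the requested rate", {
  s <- randomDnaString(500)
  expect_identical(mutateSequence(s, 0, seed = 1), s)
  # rate 1: no site retains its base (substitution excludes the current base)
  allA <- strrep("A", 200)
  m1 <- mutateSequence(allA, 1, seed = 2)
  expect_false(grepl("A", m1, fixed = TRUE))
  expect_equal(nchar(m1), 200)
  # rate 0.1 on 10 kb: observed fraction within +-0.01
  s2 <- randomDnaString(10000)
  m2 <- mutateSequence(s2, 0.1, seed = 3)
  frac <- mean(strsplit(s2, "")[[1]] != strsplit(m2, "")[[1]])
  expect_lt(abs(frac - 0.1), 0.01)
  expect_error(mutateSequence("ACGN", 0.1), "non-ACGT")
})

test_that("a single cluster with all rates zero yields identical genomes", {
  cfg <- simConfig(nClusters = 1, genomesPerCluster = 3,
                   genomeLengthRange = c(30000, 40000),
                   withinClusterSubRate = 0, betweenClusterSubRate = 0,
                   seed = 5)
  pop <- generatePopulation(cfg)
  seqs <- as.character(genomes(pop))
  expect_true(all(seqs == seqs[1]))
  d <- kmerDistanceMatrix(genomes(pop), k = 21)
  expect_true(all(as.matrix(d) == 0))
})

test_that("generation is deterministic for a fixed seed", {
  cfg <- simConfig(nClusters = 2, genomesPerCluster = 2,
                   genomeLengthRange = c(30000, 40000), seed = 9)
  p1 <- generatePopulation(cfg)
  p2 <- generatePopulation(cfg)
  expect_identical(as.character(genomes(p1)), as.character(genomes(p2)))
  expect_identical(moduleLayout(p1), moduleLayout(p2))
})

test_that("every genome carries the conserved packaging order and 1-3 exonucleases", {
  pop <- recoveryPop()
  ann <- geneAnnotations(pop)
  for (g in names(genomes(pop))) {
    sub <- ann[as.character(GenomicRanges::seqnames(ann)) == g]
    sub <- sub[order(GenomicRanges::start(sub))]
    prods <- S4Vectors::mcols(sub)$product
    packIdx <- match(c("terminase small subunit", "terminase large subunit",
                       "portal protein", "major capsid protein",
                       "scaffold protein"), prods)
    expect_false(anyNA(packIdx))
    expect_identical(packIdx, sort(packIdx))  # conserved order
    nExo <- sum(prods == "exonuclease")
    expect_gte(nExo, 1); expect_lte(nExo, 3)
  }
})

test_that("default configuration emulates the study population envelope", {
  pop <- memo("defaultPop", generatePopulation(simConfig(seed = 4)))
  w <- Biostrings::width(genomes(pop))
  expect_true(all(w >= 40000 & w <= 175000))
  gc <- vapply(as.character(genomes(pop)), phagepop:::.gcFraction, numeric(1))
  expect_true(all(gc >= 0.35 & gc <= 0.47))
})

test_that("realized G+C stays within 0.02 of each genome's target", {
  pop <- recoveryPop()
  gc <- vapply(as.character(genomes(pop)), phagepop:::.gcFraction, numeric(1))
  expect_true(all(abs(gc - gcTargets(pop)) <= 0.02))
})

test_that("with zero event probabilities clusters are structurally conserved", {
  pop <- recoveryPop()
  mods <- moduleLayout(pop)
  ann <- geneAnnotations(pop)
  for (cl in unique(trueClusters(pop))) {
    members <- names(trueClusters(pop))[trueClusters(pop) == cl]
    orders <- lapply(members, function(g)
      mods[mods$genome_id == g, c("module_id", "orientation")])
    for (o in orders[-1]) expect_equal(o, orders[[1]],
                                       ignore_attr = TRUE)
    famsets <- lapply(members, function(g)
      sort(S4Vectors::mcols(ann)$family_id[
        as.character(GenomicRanges::seqnames(ann)) == g]))
    for (f in famsets[-1]) expect_identical(f, famsets[[1]])
  }
})

test_that("between-cluster k-mer distances exceed within-cluster distances", {
  m <- as.matrix(recoveryKdist(21))
  tc <- trueClusters(recoveryPop())[rownames(m)]
  same <- outer(tc, tc, "==") & upper.tri(m)
  expect_gt(mean(m[!same & upper.tri(m)]), mean(m[same]))
  expect_gt(min(m[!same & upper.tri(m)]), max(m[same]))
})

test_that("inversion is an involution and loss removes exactly the module's genes", {
  pop <- tinyPop()
  vm <- variableModules(pop)[1]
  inv1 <- applyRearrangement(pop, "phage_01", "inversion", vm)
  expect_false(as.character(genomes(inv1)[["phage_01"]]) ==
                 as.character(genomes(pop)[["phage_01"]]))
  inv2 <- applyRearrangement(inv1, "phage_01", "inversion", vm)
  expect_identical(as.character(genomes(inv2)[["phage_01"]]),
                   as.character(genomes(pop)[["phage_01"]]))
  # inversion flips the module's gene strands in the annotation
  a0 <- geneAnnotations(pop); a1 <- geneAnnotations(inv1)
  modGenes <- S4Vectors::mcols(a0)$module_id == vm &
    as.character(GenomicRanges::seqnames(a0)) == "phage_01"
  s0 <- as.character(GenomicRanges::strand(a0))[modGenes]
  modGenes1 <- S4Vectors::mcols(a1)$module_id == vm &
    as.character(GenomicRanges::seqnames(a1)) == "phage_01"
  s1 <- as.character(GenomicRanges::strand(a1))[modGenes1]
  expect_identical(s1, rev(ifelse(s0 == "+", "-", "+")))

  nModGenes <- sum(modGenes)
  lost <- applyRearrangement(pop, "phage_01", "loss", vm)
  countGenes <- function(p, g) sum(as.character(
    GenomicRanges::seqnames(geneAnnotations(p))) == g)
  expect_equal(countGenes(pop, "phage_01") - countGenes(lost, "phage_01"),
               nModGenes)
  expect_error(applyRearrangement(pop, "phage_01", "loss", "M99"),
               "unknown module")
})

test_that("a horizontally swapped module clusters with the donor's gene families", {
  pop <- tinyPop()
  vm <- variableModules(pop)[2]
  donor <- setdiff(unique(trueClusters(pop)), trueClusters(pop)[["phage_01"]])
  swapped <- applyRearrangement(pop, "phage_01", "hgt_swap", vm,
                                donorCluster = donor)
  expect_identical(appliedEvents(swapped)$event, "hgt_swap")
  ann <- geneAnnotations(swapped)
  keep <- S4Vectors::mcols(ann)$module_id == vm
  seqs <- extractGeneSequences(genomes(swapped), ann[keep])
  fams <- clusterGeneFamilies(
    seqs, as.character(GenomicRanges::seqnames(ann[keep])))
  byGenome <- split(fams$family_id, fams$genome_id)
  donorMember <- names(trueClusters(pop))[trueClusters(pop) == donor][1]
  recipientPeer <- "phage_02"  # same true cluster as phage_01, not swapped
  expect_identical(sort(byGenome[["phage_01"]]),
                   sort(byGenome[[donorMember]]))
  expect_false(any(byGenome[["phage_01"]] %in% byGenome[[recipientPeer]]))
})
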