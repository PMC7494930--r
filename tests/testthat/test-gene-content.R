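# Ortholog family clustering, presence/absence, gene-content distances and
# the pan-genome partition.

test_that("greedy identity clustering matches the global-alignment identity rule", {
  set.seed(20)
  a <- randomDnaString(500)
  ident <- clusterGeneFamilies(
    Biostrings::DNAStringSet(c(x = a, y = a, z = a)),
    genomeIds = c("g1", "g2", "g3"))
  expect_length(unique(ident$family_id), 1)

  # ~80% identity (every 5th base substituted): below the 0.90 threshold
  b <- strsplit(a, "")[[1]]
  idx <- seq(1, 500, by = 5)
  b[idx] <- chartr("ACGT", "CAGT", b[idx])  # A<->C swaps guarantee change where A/C
  b[idx] <- ifelse(strsplit(a, "")[[1]][idx] == b[idx],
                   chartr("GT", "TG", b[idx]), b[idx])
  b <- paste(b, collapse = "")
  expect_lt(oracleGlobalIdentity(substr(a, 1, 120), substr(b, 1, 120)), 0.9)
  two <- clusterGeneFamilies(Biostrings::DNAStringSet(c(x = a, y = b)),
                             genomeIds = c("g1", "g2"))
  expect_length(unique(two$family_id), 2)
  expect_error(clusterGeneFamilies(Biostrings::DNAStringSet(), character(0)),
               "empty")
})

test_that("package identity computation agrees with a hand-rolled aligner", {
  set.seed(21)
  for (rep in 1:5) {
    a <- randomDnaString(80)
    b <- mutateSequence(a, runif(1, 0, 0.3))
    if (rep > 3) b <- paste0(substr(b, 1, 40), substr(b, 45, 80))  # deletion
    expect_equal(phagepop:::.globalIdentity(a, b), oracleGlobalIdentity(a, b),
                 tolerance = 1e-9)
  }
})

test_that("zero-divergence populations recover the true families exactly", {
  cfg <- simConfig(nClusters = 1, genomesPerCluster = 3,
                   genomeLengthRange = c(25000, 35000),
                   withinClusterSubRate = 0, betweenClusterSubRate = 0,
                   seed = 6)
  pop <- generatePopulation(cfg)
  gs <- extractGeneSequences(genomes(pop), geneAnnotations(pop))
  fams <- clusterGeneFamilies(
    gs, as.character(GenomicRanges::seqnames(geneAnnotations(pop))))
  truth <- S4Vectors::mcols(geneAnnotations(pop))$family_id
  # same partition of genes (ids differ)
  expect_equal(adjustedRandIndex(fams$family_id, truth), 1)
  # pan genome size equals the number of true families
  pa <- presenceAbsenceMatrix(fams)
  expect_equal(ncol(pa), length(unique(truth)))
})

test_that("presence/absence collapses paralogs and reflects module loss", {
  fams <- data.frame(
    gene_id = paste0("g", 1:5),
    genome_id = c("A", "A", "A", "B", "B"),
    family_id = c("f1", "f1", "f2", "f1", "f3"))
  pa <- presenceAbsenceMatrix(fams)
  expect_equal(unname(pa["A", c("f1", "f2", "f3")]), c(1L, 1L, 0L))
  expect_equal(unname(pa["B", c("f1", "f2", "f3")]), c(1L, 0L, 1L))

  pop <- tinyPop()
  vm <- variableModules(pop)[1]
  lost <- applyRearrangement(pop, "phage_01", "loss", vm)
  ann <- geneAnnotations(lost)
  truthTab <- data.frame(
    gene_id = S4Vectors::mcols(ann)$gene_id,
    genome_id = as.character(GenomicRanges::seqnames(ann)),
    family_id = S4Vectors::mcols(ann)$family_id)
  pa2 <- presenceAbsenceMatrix(truthTab, names(genomes(lost)))
  annFull <- geneAnnotations(pop)
  modFams <- unique(S4Vectors::mcols(annFull)$family_id[
    S4Vectors::mcols(annFull)$module_id == vm])
  expect_true(all(pa2["phage_01", modFams] == 0))
  otherFams <- setdiff(colnames(pa2), modFams)
  expect_true(all(pa2["phage_01", otherFams] == 1))
})

test_that("gene-content distance is Jaccard over family sets", {
  pa <- rbind(A = c(1, 1, 0), B = c(1, 0, 0), C = c(1, 1, 0))
  colnames(pa) <- paste0("f", 1:3)
  d <- as.matrix(geneContentDistance(pa))
  expect_equal(d["A", "B"], 1 / 2)   # nested {f1,f2} vs {f1}
  expect_equal(d["A", "C"], 0)
  bad <- rbind(A = c(1, 0), B = c(0, 0))
  expect_error(geneContentDistance(bad), "zero gene families")

  set.seed(22)
  r <- matrix(rbinom(40, 1, 0.6), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("f", 1:8)))
  r[, 1] <- 1
  d2 <- as.matrix(geneContentDistance(r))
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_equal(d2[i, j], binaryDistance(colnames(r)[r[i, ] == 1],
                                            colnames(r)[r[j, ] == 1]))
    }
  }
})

test_that("pan-genome partition is exhaustive, exclusive and correctly rounded", {
  pa <- rbind(A = c(1, 1, 1, 0), B = c(1, 1, 0, 0), C = c(1, 0, 0, 1))
  colnames(pa) <- paste0("f", 1:4)
  p <- partitionPanGenome(pa)
  expect_equal(p$core + p$softcore + p$shell + p$cloud, p$pan)
  expect_equal(p$core, 1)          # f1 in all genomes
  expect_equal(p$core_pct + p$accessory_pct, 100)

  all1 <- matrix(1, 3, 5, dimnames = list(letters[1:3], paste0("f", 1:5)))
  pAll <- partitionPanGenome(all1)
  expect_equal(pAll$core_pct, 100)
  expect_equal(pAll$accessory_pct, 0)

  set.seed(23)
  for (rep in 1:10) {
    r <- matrix(rbinom(60, 1, runif(1, 0.2, 0.9)), nrow = 6)
    colnames(r) <- paste0("f", seq_len(ncol(r)))
    rownames(r) <- paste0("g", 1:6)
    pr <- partitionPanGenome(r)
    expect_equal(pr$core + pr$softcore + pr$shell + pr$cloud, pr$pan)
  }
})

test_that("raising the identity threshold never decreases the family count", {
  set.seed(24)
  base <- vapply(1:4, function(i) randomDnaString(300), character(1))
  seqs <- c(base,
            vapply(base, function(s) mutateSequence(s, 0.05), character(1)),
            vapply(base, function(s) mutateSequence(s, 0.15), character(1)))
  names(seqs) <- paste0("gene", seq_along(seqs))
  gms <- rep(c("g1", "g2", "g3"), each = 4)
  counts <- vapply(c(0.7, 0.85, 0.95, 0.999), function(th)
    length(unique(clusterGeneFamilies(Biostrings::DNAStringSet(seqs), gms,
                                      identityThreshold = th)$family_id)),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
})
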