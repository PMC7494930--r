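# Gene-order locally collinear blocks.

# small hand-built annotation: two genomes, families f1..f6 in order
mkAnnot <- function(orders, strands = NULL) {
  gid <- rep(names(orders), lengths(orders))
  fams <- unlist(orders, use.names = FALSE)
  st <- if (is.null(strands)) rep("+", length(fams))
        else unlist(strands, use.names = FALSE)
  pos <- unlist(lapply(lengths(orders), function(n)
    seq(1, by = 1000, length.out = n)), use.names = FALSE)
  gr <- GenomicRanges::GRanges(gid, IRanges::IRanges(pos, pos + 500),
                               strand = st)
  S4Vectors::mcols(gr)$gene_id <- paste0(gid, "_", seq_along(fams))
  S4Vectors::mcols(gr)$family_id <- fams
  gr
}

test_that("identical gene orders give a single block spanning all families", {
  ann <- mkAnnot(list(g1 = paste0("f", 1:6), g2 = paste0("f", 1:6)))
  lc <- findLcbs(ann)
  expect_equal(nrow(lc$blocks), 1)
  expect_equal(lc$blocks$n_genes, 6)
  expect_equal(unname(lcbCensus(lc)$counts), c(1L, 1L))
})

test_that("an inverted module splits the comparison into three blocks", {
  fams <- paste0("f", 1:9)
  inv <- c(fams[1:3], rev(fams[4:6]), fams[7:9])
  strands <- list(g1 = rep("+", 9),
                  g2 = c(rep("+", 3), rep("-", 3), rep("+", 3)))
  ann <- mkAnnot(list(g1 = fams, g2 = inv), strands)
  lc <- findLcbs(ann)
  expect_equal(nrow(lc$blocks), 3)
  expect_setequal(lc$blocks$n_genes, c(3, 3, 3))
  occ <- lc$occurrences
  # the middle block occurs reversed in g2
  midBlock <- lc$blocks$block_id[grepl("f4", lc$blocks$families)]
  orient <- occ$orientation[occ$block_id == midBlock]
  expect_setequal(orient, c(1L, -1L))
})

test_that("module loss splits flanking blocks by genome membership", {
  fams <- paste0("f", 1:9)
  ann <- mkAnnot(list(g1 = fams, g2 = fams, g3 = fams[-(4:6)]))
  lc <- findLcbs(ann)
  cen <- lcbCensus(lc, c("g1", "g2", "g3"))
  expect_equal(unname(cen$counts), c(3L, 3L, 2L))
  # the lost module's block excludes g3
  lostBlock <- lc$blocks$block_id[grepl("f4", lc$blocks$families)]
  expect_false("g3" %in% lc$occurrences$genome_id[
    lc$occurrences$block_id == lostBlock])
})

test_that("a tandem repeat yields one block occurrence per copy", {
  fams <- paste0("f", 1:6)
  rep2 <- c(fams[1:3], fams[4:6], fams[4:6])
  ann <- mkAnnot(list(g1 = fams, g2 = rep2))
  lc <- findLcbs(ann)
  cen <- lcbCensus(lc, c("g1", "g2"))
  expect_equal(unname(cen$counts["g2"] - cen$counts["g1"]), 1L)
  repBlock <- lc$blocks$block_id[grepl("f4", lc$blocks$families)]
  expect_equal(sum(lc$occurrences$block_id == repBlock &
                     lc$occurrences$genome_id == "g2"), 2)
})

test_that("simulated rearrangements place block boundaries at module edges", {
  pop <- tinyPop()
  vm <- variableModules(pop)[1]
  inv <- applyRearrangement(pop, "phage_01", "inversion", vm)
  lc <- findLcbs(geneAnnotations(inv))
  ann <- geneAnnotations(inv)
  modFams <- unique(S4Vectors::mcols(ann)$family_id[
    S4Vectors::mcols(ann)$module_id == vm])
  # one block is exactly the inverted module
  blockFams <- lapply(strsplit(lc$blocks$families, ","), function(x)
    sub("\\([+-]\\)$", "", x))
  expect_true(any(vapply(blockFams, function(f) setequal(f, modFams),
                         logical(1))))
  # re-inverting restores the single-block solution
  back <- applyRearrangement(inv, "phage_01", "inversion", vm)
  lcBack <- findLcbs(geneAnnotations(back))
  expect_equal(nrow(lcBack$blocks), 1)
})

test_that("census is invariant to genome input order and genes join one block", {
  fams <- paste0("f", 1:8)
  ann <- mkAnnot(list(g1 = fams, g2 = fams[-(3:4)], g3 = fams))
  lc1 <- findLcbs(ann)
  perm <- mkAnnot(list(g3 = fams, g1 = fams, g2 = fams[-(3:4)]))
  lc2 <- findLcbs(perm)
  c1 <- lcbCensus(lc1, c("g1", "g2", "g3"))$counts
  c2 <- lcbCensus(lc2, c("g1", "g2", "g3"))$counts
  expect_identical(c1, c2)
  # coverage: within a genome, block occurrences never overlap
  occ <- lc1$occurrences
  for (g in unique(occ$genome_id)) {
    sub <- occ[occ$genome_id == g, ]
    covered <- unlist(Map(seq, sub$start_index, sub$end_index))
    expect_false(anyDuplicated(covered) > 0)
  }
  expect_error(findLcbs(mkAnnot(list(g1 = c("f1", NA), g2 = c("f1", "f2")))),
               "family_id")
})
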