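# Progressive alignment, TN93 distances, neighbor joining, bootstrap.

test_that("progressive alignment handles identity, single indels, and bounds", {
  same <- c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "ACGTACGTAC")
  aln <- progressiveAlign(same)
  expect_false(any(grepl("-", aln, fixed = TRUE)))

  two <- progressiveAlign(c(a = "ACGTACGT", b = "ACGACGT"))
  expect_equal(unique(nchar(two)), 8)
  expect_equal(sum(strsplit(two[["b"]], "")[[1]] == "-"), 1)
  expect_false(grepl("-", two[["a"]], fixed = TRUE))

  set.seed(30)
  seqs <- c(a = randomDnaString(60), b = randomDnaString(70),
            c = randomDnaString(65), d = randomDnaString(80))
  aln2 <- progressiveAlign(seqs)
  expect_gte(unique(nchar(aln2)), 80)
  # de-gapping returns the inputs
  for (nm in names(seqs))
    expect_identical(gsub("-", "", aln2[[nm]], fixed = TRUE),
                     unname(seqs[nm]))
  expect_error(progressiveAlign(c(a = "ACGT")), "at least 2")
})

test_that("TN93 distance is zero on identical rows and errors at saturation", {
  est <- tn93Distance("ACGTACGT", "ACGTACGT")
  expect_equal(est$d, 0)
  expect_equal(est$P1 + est$P2 + est$Q, 0)
  expect_error(tn93Distance(strrep("A", 50), strrep("C", 50)), "satur")
})

test_that("TN93 reduces to the K2P closed form under equal base frequencies", {
  # rows with equal pooled frequencies, P1 = P2 = 0, Q = 0.2:
  # 100 sites, 25 each of A/C/G/T; 10 A->T and 10 T->A transversions keep
  # the pooled composition uniform
  rowA <- paste(rep(c("A", "C", "G", "T"), each = 25), collapse = "")
  vb <- strsplit(rowA, "")[[1]]
  vb[1:10] <- "T"            # A -> T
  vb[76:85] <- "A"           # T -> A
  rowB <- paste(vb, collapse = "")
  est <- tn93Distance(rowA, rowB)
  expect_equal(est$Q, 0.2)
  expect_equal(est$P1, 0); expect_equal(est$P2, 0)
  expect_equal(unname(est$freqs), rep(0.25, 4))
  P <- 0; Q <- 0.2
  k2p <- -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
  expect_equal(est$d, k2p, tolerance = 1e-12)
})

test_that("TN93 agrees with an independent implementation on random pairs", {
  set.seed(31)
  for (rep in 1:5) {
    a <- randomDnaString(600, gc = runif(1, 0.3, 0.6))
    b <- evolveJC(a, runif(1, 0.02, 0.3))
    ours <- tn93Distance(a, b)$d
    bin <- ape::as.DNAbin(list(a = strsplit(tolower(a), "")[[1]],
                               b = strsplit(tolower(b), "")[[1]]))
    ref <- ape::dist.dna(bin, model = "TN93", pairwise.deletion = TRUE)
    expect_equal(ours, as.numeric(ref), tolerance = 1e-8)
    # correction inequality: model distance >= observed p-distance
    p <- as.numeric(ape::dist.dna(bin, model = "raw"))
    expect_gte(ours, p - 1e-12)
  }
})

test_that("TN93 recovers the generating divergence from long simulated pairs", {
  set.seed(32)
  a <- randomDnaString(50000)
  b <- evolveJC(a, 0.1)
  expect_lt(abs(tn93Distance(a, b)$d - 0.1), 0.01)
})

test_that("NJ solves the three-taxon case and recovers additive trees exactly", {
  m <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(m)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  # three-point solution: la = 1, lb = 2, lc = 3
  lens <- tr$edge.length[match(1:3, tr$edge[, 2])]
  expect_equal(sort(lens), c(1, 2, 3))

  set.seed(33)
  for (n in c(4, 6, 8)) {
    true <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    true <- ape::unroot(true)
    dm <- stats::as.dist(ape::cophenetic.phylo(true))
    got <- njTree(dm)
    expect_equal(rfDistance(got, true), 0)
    expect_lt(branchScore(got, true), 1e-8)
  }
})

test_that("NJ topology matches an independent implementation on random matrices", {
  set.seed(34)
  for (rep in 1:5) {
    n <- 7
    m <- matrix(runif(n * n, 0.1, 1), n, n)
    m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(letters[1:n], letters[1:n])
    ours <- njTree(stats::as.dist(m))
    ref <- ape::nj(stats::as.dist(m))
    expect_equal(rfDistance(ours, ref), 0)
  }
})

test_that("NJ on ultrametric input reproduces the UPGMA topology", {
  pop <- recoveryPop()
  d <- recoveryKdist(10)
  hc <- upgma(d)
  um <- copheneticDistances(hc)  # exactly ultrametric, additive on the tree
  expect_equal(rfDistance(njTree(um), dendrogramToPhylo(hc)), 0)
})

test_that("bootstrap supports are seed-deterministic with sane extremes", {
  set.seed(35)
  base <- randomDnaString(300)
  seqs <- c(a = evolveJC(base, 0.02), b = evolveJC(base, 0.02),
            c = evolveJC(base, 0.4), d = evolveJC(base, 0.4),
            e = evolveJC(base, 0.02))
  aln <- progressiveAlign(seqs)
  t1 <- bootstrapSupport(aln, nReplicates = 25, seed = 5)
  t2 <- bootstrapSupport(aln, nReplicates = 25, seed = 5)
  expect_identical(attr(t1, "supports"), attr(t2, "supports"))
  one <- bootstrapSupport(aln, nReplicates = 1, seed = 6)
  expect_true(all(attr(one, "supports") %in% c(0, 100)))
  expect_error(bootstrapSupport(aln, nReplicates = 0), ">= 1")
})

test_that("well-separated clusters get high support on every between-cluster edge", {
  pop <- recoveryPop()
  aln <- recoveryMarkerAln()
  tree <- bootstrapSupport(aln, nReplicates = 100, seed = 17)
  sup <- attr(tree, "supports")
  truth <- trueClusters(pop)
  allIds <- names(truth)
  for (cl in unique(truth)) {
    members <- sort(names(truth)[truth == cl])
    keyIn <- paste(members, collapse = "|")
    keyOut <- paste(sort(setdiff(allIds, members)), collapse = "|")
    val <- c(sup[keyIn], sup[keyOut])
    val <- val[!is.na(val)]
    expect_gte(length(val), 1)  # the cluster is monophyletic in the tree
    expect_gte(max(val), 95)
  }
})
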