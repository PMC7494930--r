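# Shared fixtures (memoized) and independent brute-force oracles.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# the standard synthetic recovery population: 3 clusters x 5 genomes,
# within 0.01 / between 0.15 substitutions per site
recoveryConfig <- function(seed = 11) {
  simConfig(nClusters = 3, genomesPerCluster = 5,
            genomeLengthRange = c(44324, 60000), seed = seed)
}
recoveryPop <- function() memo("recoveryPop", generatePopulation(recoveryConfig()))
recoveryKdist <- function(k) memo(paste0("kdist", k),
  kmerDistanceMatrix(genomes(recoveryPop()), k = k))
recoveryFamilies <- function() memo("families", {
  pop <- recoveryPop()
  gs <- extractGeneSequences(genomes(pop), geneAnnotations(pop))
  clusterGeneFamilies(gs, as.character(GenomicRanges::seqnames(geneAnnotations(pop))))
})
recoveryMarkerAln <- function() memo("markerAln",
  progressiveAlign(markerSequences(recoveryPop(), "terminase large subunit")))

# small population for structural tests (fast)
tinyPop <- function() memo("tinyPop", generatePopulation(
  simConfig(nClusters = 2, genomesPerCluster = 2,
            genomeLengthRange = c(30000, 40000), seed = 3)))

variableModules <- function(pop) {
  els <- pop@elements$genomes[[1]]
  unique(els$module_id[!is.na(els$module_type) &
                         els$module_type == "variable"])
}

# ---- independent oracles ---------------------------------------------------

# canonical k-mers by explicit per-window enumeration
oracleCanonicalKmers <- function(seq, k) {
  rc1 <- function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  out <- character(0)
  for (i in seq_len(nchar(seq) - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    if (grepl("N", w)) next
    r <- rc1(w)
    out <- c(out, if (w <= r) w else r)
  }
  unique(out)
}

# brute-force average linkage: recompute the full average inter-cluster
# distance at every step from the original matrix
oracleAverageLinkage <- function(m) {
  m <- as.matrix(m)
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestD <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- mean(m[clusters[[i]], clusters[[j]]])
        if (d < bestD) { bestD <- d; best <- c(i, j) }
      }
    }
    heights <- c(heights, bestD)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# all non-trivial bipartitions of a phylo tree by edge removal (brute force,
# independent of the package's traversal code)
oracleBipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  out <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    # tips on the child side of edge e, found by graph flood fill
    edges <- tree$edge[-e, , drop = FALSE]
    reach <- tree$edge[e, 2]
    repeat {
      nxt <- unique(c(edges[edges[, 1] %in% reach, 2],
                      edges[edges[, 2] %in% reach, 1]))
      nxt <- union(reach, nxt)
      if (length(nxt) == length(reach)) break
      reach <- nxt
    }
    side <- tree$tip.label[reach[reach <= n]]
    if (length(side) < 2 || length(side) > n - 2) next
    ref <- sort(tree$tip.label)[1]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

# simple Needleman-Wunsch global alignment score/identity oracle for short
# sequences (match +1, mismatch -1, linear gap -2)
oracleGlobalIdentity <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -2 * (0:n); S[1, ] <- -2 * (0:m)
  for (i in 1:n) {
    for (j in 1:m) {
      S[i + 1, j + 1] <- max(S[i, j] + ifelse(av[i] == bv[j], 1, -1),
                             S[i, j + 1] - 2, S[i + 1, j] - 2)
    }
  }
  # traceback to count matches and alignment length
  i <- n; j <- m; matches <- 0; len <- 0
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + ifelse(av[i] == bv[j], 1, -1)) {
      matches <- matches + (av[i] == bv[j]); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 2) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    len <- len + 1
  }
  matches / len
}

# evolve a sequence for d expected substitutions/site under Jukes-Cantor (a
# TN93 special case): per-site change probability 3/4 (1 - exp(-4 d / 3))
evolveJC <- function(seq, d) {
  p <- 3 / 4 * (1 - exp(-4 * d / 3))
  v <- strsplit(seq, "")[[1]]
  hit <- runif(length(v)) < p
  off <- sample.int(3, sum(hit), replace = TRUE)
  bases <- c("A", "C", "G", "T")
  v[hit] <- bases[((match(v[hit], bases) - 1 + off) %% 4) + 1]
  paste(v, collapse = "")
}

randomDnaString <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
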