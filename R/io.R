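# Readers/writers for the standard formats the pipeline touches, plus the
# packaged fixtures of the two printed summary tables.
#
# Conventions: coordinates are 1-based inclusive throughout (GFF3); FASTA is
# wrapped at 80 columns; distance matrices round-trip through PHYLIP square
# format at 6 decimals; trees through Newick via ape.

#' Read phage genomes from a FASTA file
#'
#' Sequences are uppercased on input; the alphabet must be within A/C/G/T/N.
#'
#' @param path FASTA file.
#' @return A named [Biostrings::DNAStringSet] (empty for an empty file).
#' @export
readFastaGenomes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  nonEmpty <- which(nzchar(trimws(lines)))
  if (!length(nonEmpty)) return(Biostrings::DNAStringSet())
  if (!startsWith(lines[nonEmpty[1]], ">"))
    stop("malformed FASTA: line ", nonEmpty[1], " is not a header")
  x <- Biostrings::readDNAStringSet(path)
  x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  # keep only the first whitespace-delimited token as the id
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate genome ids in ", path)
  ok <- grepl("^[ACGTN]*$", as.character(x))
  if (!all(ok))
    stop("genome '", names(x)[!ok][1], "' contains bases outside A/C/G/T/N")
  if (any(Biostrings::width(x) == 0))
    stop("empty sequence for genome '", names(x)[Biostrings::width(x) == 0][1], "'")
  x
}

#' Write phage genomes to FASTA (80-column wrapping)
#'
#' @param genomes a named [Biostrings::DNAStringSet] (or named character).
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeFastaGenomes <- function(genomes, path) {
  if (is.character(genomes))
    genomes <- Biostrings::DNAStringSet(genomes)
  if (is.null(names(genomes)) || anyDuplicated(names(genomes)))
    stop("genomes must have unique names")
  Biostrings::writeXStringSet(genomes, path, width = 80L)
  invisible(path)
}

.parseGffAttributes <- function(attr) {
  fields <- strsplit(attr, ";", fixed = TRUE)
  lapply(fields, function(f) {
    f <- f[nzchar(f)]
    kv <- strsplit(f, "=", fixed = TRUE)
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
    names(vals) <- vapply(kv, `[[`, character(1), 1)
    vals
  })
}

#' Read CDS gene annotations from a GFF3 file
#'
#' Parses CDS features into a [GenomicRanges::GRanges] with 1-based inclusive
#' coordinates and metadata columns \code{gene_id} (from the \code{ID}
#' attribute), \code{product}, \code{family_id} and \code{module_id} (NA when
#' the attribute is absent).
#'
#' @param path GFF3 file.
#' @return A [GenomicRanges::GRanges].
#' @export
readGff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(GenomicRanges::GRanges())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 9L)
  if (length(bad))
    stop("malformed GFF3: expected 9 tab-separated columns at record ", bad[1])
  m <- do.call(rbind, parts)
  keep <- m[, 3] == "CDS"
  m <- m[keep, , drop = FALSE]
  start <- as.integer(m[, 4]); end <- as.integer(m[, 5])
  if (any(is.na(start)) || any(is.na(end)) || any(start < 1))
    stop("malformed GFF3: non-numeric or non-positive coordinates")
  if (any(end < start))
    stop("invalid feature: end < start at record ", which(end < start)[1])
  attrs <- .parseGffAttributes(m[, 9])
  getA <- function(key) vapply(attrs, function(a)
    if (key %in% names(a)) a[[key]] else NA_character_, character(1))
  gr <- GenomicRanges::GRanges(
    seqnames = m[, 1],
    ranges = IRanges::IRanges(start = start, end = end),
    strand = ifelse(m[, 7] %in% c("+", "-"), m[, 7], "*"))
  mcols(gr)$gene_id <- getA("ID")
  mcols(gr)$product <- getA("product")
  mcols(gr)$family_id <- getA("family_id")
  mcols(gr)$module_id <- getA("module_id")
  gr
}

#' Write CDS gene annotations to GFF3
#'
#' @param annot a [GenomicRanges::GRanges] with metadata columns
#'   \code{gene_id} and optionally \code{product}, \code{family_id},
#'   \code{module_id}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeGff3 <- function(annot, path) {
  mc <- mcols(annot)
  if (is.null(mc$gene_id)) stop("'annot' needs a gene_id metadata column")
  attr1 <- paste0("ID=", mc$gene_id)
  for (key in c("product", "family_id", "module_id")) {
    v <- mc[[key]]
    if (!is.null(v))
      attr1 <- paste0(attr1, ifelse(is.na(v), "",
                                    paste0(";", key, "=", v)))
  }
  lines <- paste(
    as.character(seqnames(annot)), "phagepop", "CDS",
    start(annot), end(annot), ".",
    as.character(strand(annot)), "0", attr1, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Extract strand-corrected gene sequences
#'
#' Slices each annotated gene out of its genome and reverse-complements
#' minus-strand genes, so every returned sequence reads in the coding sense.
#'
#' @param genomes named [Biostrings::DNAStringSet].
#' @param annot [GenomicRanges::GRanges] whose seqnames are genome ids.
#' @return A [Biostrings::DNAStringSet] named by gene id.
#' @export
extractGeneSequences <- function(genomes, annot) {
  gid <- as.character(seqnames(annot))
  missing <- setdiff(unique(gid), names(genomes))
  if (length(missing))
    stop("annotation references unknown genome(s): ",
         paste(missing, collapse = ", "))
  out <- Biostrings::DNAStringSet(vapply(seq_along(annot), function(i)
    as.character(Biostrings::subseq(genomes[[gid[i]]],
                                    start(annot)[i], end(annot)[i])),
    character(1)))
  neg <- as.character(strand(annot)) == "-"
  if (any(neg))
    out[neg] <- Biostrings::reverseComplement(out[neg])
  names(out) <- mcols(annot)$gene_id
  out
}

#' Write a synthetic population to disk
#'
#' Writes genomes as FASTA, annotations as GFF3 (with \code{family_id} and
#' \code{module_id} attributes), and truth tables (clusters, module layout,
#' events) as TSV.
#'
#' @param pop a [PhagePopulation-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
writePopulation <- function(pop, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    fasta = file.path(dir, "genomes.fasta"),
    gff = file.path(dir, "genes.gff3"),
    clusters = file.path(dir, "true_clusters.tsv"),
    modules = file.path(dir, "module_layout.tsv"),
    events = file.path(dir, "events.tsv"))
  writeFastaGenomes(pop@genomes, paths["fasta"])
  writeGff3(pop@genes, paths["gff"])
  utils::write.table(
    data.frame(genome_id = names(pop@clusters), cluster = pop@clusters),
    paths["clusters"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pop@modules, paths["modules"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(pop@events, paths["events"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Packaged phage characteristics table (38 records)
#'
#' The printed per-phage summary of the 38-coliphage study population: name,
#' sampling region and farm, host strain, genome size, G+C, CDS count,
#' closest reference phage, taxonomy (family/subfamily/genus) and the four
#' cluster labels (whole-genome, terminase large subunit, portal protein,
#' exonuclease). One genome-size entry (Phage 55, 1,699,535 bp) is carried
#' verbatim but flagged \code{suspect_typo}, since the population's stated
#' maximum genome size is 173,384 bp; range computations should exclude
#' flagged rows (see [summarizePopulation()]).
#'
#' @return A data.frame with 38 rows.
#' @export
loadPhageTable <- function() {
  path <- system.file("extdata", "phage_records.tsv", package = "phagepop",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Packaged per-cluster pan-genome table (8 rows)
#'
#' Printed core/accessory/pan gene counts and LCB count ranges for the eight
#' phage (sub)clusters A1, A2, A3, B, C, D, E, F.
#'
#' @return A data.frame with 8 rows.
#' @export
loadPanGenomeTable <- function() {
  path <- system.file("extdata", "pan_genome_summary.tsv", package = "phagepop",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write/read a square PHYLIP distance matrix
#'
#' Distances are written at 6 decimals; labels must be unique.
#'
#' @param d a \code{dist} or symmetric matrix with labels.
#' @param path file path.
#' @return \code{writePhylipDist} invisibly returns \code{path};
#'   \code{readPhylipDist} returns a \code{dist}.
#' @export
writePhylipDist <- function(d, path) {
  m <- as.matrix(d)
  labels <- rownames(m)
  if (is.null(labels) || anyDuplicated(labels))
    stop("distance matrix must have unique labels")
  lines <- c(sprintf("%5d", nrow(m)),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(format(labels[i], width = 10),
                       sprintf("%.6f", m[i, ])), collapse = "  "),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writePhylipDist
#' @export
readPhylipDist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  toks <- strsplit(trimws(lines[1 + seq_len(n)]), "\\s+")
  labels <- vapply(toks, `[[`, character(1), 1)
  m <- do.call(rbind, lapply(toks, function(x) as.numeric(x[-1])))
  dimnames(m) <- list(labels, labels)
  stats::as.dist(m)
}

#' Write/read a phylogenetic tree in Newick format
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()]; round-trips
#' preserve topology, branch lengths and internal (support) labels.
#'
#' @param tree an [ape::phylo] object.
#' @param path file path.
#' @return \code{writeNewick} invisibly returns \code{path}; \code{readNewick}
#'   returns a [ape::phylo].
#' @export
writeNewick <- function(tree, path) {
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) ape::read.tree(path)
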