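---
title: "Methods: phage population diversity analysis with phagepop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phage population diversity analysis with phagepop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagepop)
```

# Scope and model

`phagepop` analyses the diversity of a population of assembled dsDNA phage
genomes along four complementary routes and checks their agreement:

1. **Alignment-free whole-genome comparison.** Each genome is reduced to its
   set of canonical k-mers (the lexicographically smaller of each window and
   its reverse complement, so profiles are strand-invariant; windows
   containing N are skipped). Pairwise dissimilarity is the binary (Jaccard)
   distance $d = |A \triangle B| / |A \cup B|$ — joint absences carry no
   information about relatedness and are ignored. Defaults are $k=10$ and
   $k=21$: $k=10$ saturates more slowly with divergence and is the
   conventional choice for dendrogram figures; $k=21$ is long enough that
   shared words are effectively homologous, which is the right regime for
   similarity-based taxonomy.
2. **Gene-content comparison.** Genes are grouped into ortholog families by
   deterministic greedy clustering: genes are processed longest-first (ties
   by gene id) and each joins the first family whose representative it
   matches at $\ge$ 90% global nucleotide identity, else founds a new
   family. Identity is matches / alignment length under global alignment
   with match $+1$, mismatch $-1$, gap $-2$, so gaps count against identity.
   The genome-by-family presence/absence matrix (paralogs collapse to a
   single presence) yields the same Jaccard distance as above, and the
   Roary-convention pan-genome partition by family prevalence $p$:
   core $p \ge 0.99$, softcore $0.95 \le p < 0.99$, shell
   $0.15 \le p < 0.95$, cloud $p < 0.15$. With fewer than 20 genomes the
   two upper cut-points coincide with "present in every genome"; percentage
   summaries round half-up, matching printed-table conventions.
3. **Cluster calling.** Distance matrices are clustered by UPGMA. A merge is
   placed at the average inter-cluster distance itself — not half of it —
   which is the convention under which published cut-off heights on binary
   distance dendrograms (0.82, 0.81, 0.58, 0.52, 0.39, 0.36) are read
   directly off the tree. Clusters at a cut height are the maximal groups
   whose internal merges all lie strictly below the height; labels (A, B,
   C, ... with subclusters A1, A2, ...) are assigned by decreasing cluster
   size, then lexicographically smallest member. Letter identity is
   presentation only; every claim in the package is about the partition.
   Cut heights are user parameters: the package deliberately provides no
   automatic height selection.
4. **Marker-gene phylogenies.** The terminase large subunit, portal protein
   and exonuclease genes are semi-conserved single-copy (or low-copy)
   markers for tailed phages. Marker sequences are aligned progressively
   (UPGMA guide tree on p-distances of pairwise global alignments; profiles
   merged leaf-to-root with affine-gap profile alignment, match $+1$,
   mismatch $-1$, gap open $-5$, extend $-1$), pairwise distances follow the
   closed-form Tamura–Nei (TN93) estimator, trees are built by Saitou–Nei
   neighbor joining, and supports come from column-resampling bootstrap.
   Genomes carrying several exonuclease copies contribute one leaf per copy
   (`genome__copyN`), which reproduces the known failure mode where copy
   choice fragments clusters.

Tree agreement is quantified by the Robinson–Foulds distance (non-trivial
bipartitions present in exactly one tree) and the Kuhner–Felsenfeld branch
score (root of the summed squared branch-length differences over the union
of bipartitions, pendant edges included — the scaling identity
$\mathrm{bs}(t, \lambda t) = (\lambda - 1)\sqrt{\sum \ell^2}$ only holds
with pendant edges in the sum). Partition agreement uses the adjusted Rand
index.

## Distance-based rather than likelihood tree inference

Marker trees use TN93 + NJ rather than maximum likelihood. This is the one
intentional methodological substitution in the package: NJ is
deterministic, exact on additive distances, and at marker-gene scale the
cluster-level conclusions (memberships, between-cluster support) are
insensitive to the choice, while likelihood optimisation would add a
stochastic, slow dependency. TN93 is kept as the substitution model, with
pairwise deletion of gap/ambiguous columns (robust for mosaic genes, where
complete deletion can discard most columns) and base frequencies pooled
from each pair of rows (a symmetric estimator). Negative NJ branch lengths
are clamped to zero with the deficit moved to the sister branch, the
standard repair. Saturated pairs (a TN93 logarithm argument $\le 0$) raise
an explicit error rather than returning NaN; bootstrap replicates that
saturate are dropped from the support denominator.

## Genus assignment

Genus calls follow the ICTV-style demarcation of a group sharing more than
50% nucleotide similarity. Whole-genome similarity is operationalised as
the Sørensen–Dice coefficient over canonical 21-mer sets,
$2|K_a \cap K_b| / (|K_a| + |K_b|)$, a standard alignment-free proxy. Each
query inherits genus (and family/subfamily) from its best-scoring reference
when similarity strictly exceeds the threshold, and is otherwise flagged
`NEW_GENUS_CANDIDATE`. The strict inequality means a query with zero
similarity to every reference is never assigned, whatever the threshold.

## Gene-order collinear blocks

Synteny is assessed at gene-order level: a locally collinear block (LCB) is
a maximal run of consecutive shared gene families with consistent order and
orientation across at least two genomes. Detection is by adjacency
breakpoints: families are first partitioned by the exact set of genomes
containing them (a module lost from one genome necessarily splits its
flanks into different blocks); within a class, two families chain when, in
every genome of the class, every occurrence of either family is immediately
adjacent to the other in the full gene order with a consistent relative
orientation. An inversion breaks both boundary adjacencies (prefix /
inverted module / suffix: three blocks); a tandem repeat produces one block
occurrence per copy, because the copy-boundary adjacency exists only in the
repeat-bearing genome. A genome-unique gene inserted inside an otherwise
shared run also breaks it — blocks are conservative. Blocks shorter than
`minBlockGenes` (default 2: one shared gene is not evidence of
collinearity) are discarded. Nucleotide-level alignment blocks and any
analogue of an alignment LCB weight parameter are out of scope, so printed
LCB counts from nucleotide-level tools are emulation references, not
targets.

# The synthetic population generator

Real phage populations for this analysis would require assembling raw
sequencing runs; instead the package carries a simulator whose ground truth
(cluster labels, gene families, module layout, applied events) makes every
stage testable. The generator emulates a population of tailed dsDNA
coliphages:

* genomes are linear strings of 44,324–173,384 bp (the span of the study
  population this design emulates) with per-cluster G+C targets drawn from
  35.5–46.4%; circular permutation is ignored because every downstream
  measure is order- or set-based;
* genes are 300–3,000 bp in multiples of 3 (length $300 + 3X$ with a
  geometric-like tail of mean $\approx$ 250 bp, giving the short-gene
  distribution that yields realistic CDS counts of roughly 70–280 per
  genome), separated by 2–200 bp spacers, organised into modules of 4–8
  genes;
* every genome opens with the conserved DNA-packaging module in fixed
  order — terminase small subunit, terminase large subunit, portal protein,
  major capsid protein, scaffold protein — followed by a nuclease module
  with 1–3 exonuclease paralogs (copy number fixed per cluster, emulating
  the observed cluster-associated copy variation; paralogs are pre-diverged
  at 0.25 substitutions/site so they are distinct families at any sensible
  identity threshold);
* a single root genome is mutated into cluster ancestors at
  `betweenClusterSubRate` (default 0.15 substitutions/site), followed by a
  G+C tuning pass (targeted A/T$\leftrightarrow$G/C substitutions) to the
  cluster's G+C target; each genome is its cluster ancestor mutated at
  `withinClusterSubRate` (default 0.01). Substitutions are uniform over the
  three alternative bases and never insert or delete; realized G+C
  therefore lands within $\pm 0.02$ of target (binomial noise at 50 kb is
  $\approx 0.002$);
* mosaic events are applied per genome and recorded: horizontal swap of a
  variable module with another cluster's ancestral version, module
  inversion (reverse-complement, strand flips, an involution), module loss,
  and tandem repeat regions (duplication of one module — which is exactly
  what makes LCB counts vary between genomes of one cluster). All event
  probabilities default to 0: the baseline study condition is
  substitution-only divergence, and events are switched on explicitly by
  tests and analyses that need them.

The published divergence structure of such populations is not directly
reported anywhere, so the within/between defaults (0.01 / 0.15) were chosen
once for separability — between-cluster k-mer distances must exceed
within-cluster ones at both k values — rather than calibrated to data, and
are not revisited. `nVariableModules` is a minimum: variable modules are
appended until the genome reaches a target length drawn from
`genomeLengthRange`, which is the binding constraint.

What the simulator does **not** emulate: real promoter/tRNA architecture,
lifestyle genes, assembly artefacts, incomplete genomes, nucleotide-level
indels inside genes (the aligner's gap machinery is exercised by
marker-gene alignments, not by the generator), and gradual homology decay
across many clusters. Passing recovery tests therefore demonstrates that
the implementations are correct under clean, well-separated conditions, not
that the method resolves borderline real-world populations.

All randomness flows from one seed in a documented call order (root layout,
cluster G+C targets, exonuclease copy numbers, cluster ancestors, genomes,
then per-genome events in the order swap, inversion, loss, repeat), so a
configuration reproduces byte-identical populations.

# Numerical and implementation choices

* **UPGMA** is delegated to `stats::hclust(method = "average")`, whose
  merge heights are exactly the average inter-cluster distances; a
  brute-force average-linkage oracle in the test suite pins this down. Cut
  calling is implemented in-package because the strict "merges below the
  height" rule differs from `cutree`'s inclusive behaviour at exact ties.
* **Greedy family clustering** screens candidate representatives before
  aligning: an exact length-ratio bound (identity cannot exceed
  shorter/longer) and a conservative shared-12-mer prefilter (pairs sharing
  under 5% of words cannot plausibly reach 90% identity — at 90% identity
  the expected shared fraction is $0.9^{12} \approx 0.28$). Only the
  alignment decides membership.
* **Determinism** everywhere: tie-breaks by label order (UPGMA, NJ, genus
  ties by reference id), fixed processing orders, one RNG stream per seed.
  `runPipeline()` writes an md5 manifest; rerunning with the same seed is
  bit-identical.
* **Problem sizes.** Simulation-based analyses and the acceptance script
  use 3 clusters x 5 genomes of 44–60 kb (and 2–6 genomes of 25–40 kb for
  structural and determinism checks), this package's chosen desk-scale
  study condition; the default `simConfig()` keeps the full 44–173 kb
  emulation envelope and is exercised in generation-level tests.
* **Degenerate inputs** raise typed errors rather than propagating NaN:
  empty presence sets (Jaccard undefined), genomes shorter than k,
  saturated TN93 pairs, NA distances in clustering, leaf-set mismatches in
  tree comparison, unknown modules in rearrangement calls.

# A worked run

```{r, eval = FALSE}
cfg <- simConfig(nClusters = 3, genomesPerCluster = 5,
                 genomeLengthRange = c(44324, 60000), seed = 11)
report <- runPipeline(cfg, bootstrapReplicates = 100, seed = 7)
round(report$concordance, 2)       # pairwise ARI between all cluster calls
report$panGenome                   # per-cluster core/softcore/shell/cloud
head(report$taxonomy)              # genus calls against per-cluster references
```

On this clean synthetic population every route — k-mer at both k values,
gene content, and each of the three markers — recovers the true partition
(all pairwise ARI 1), between-cluster marker edges carry 100% bootstrap
support, and genus recovery against one reference per cluster is complete;
withholding a cluster's reference flags all its members as
`NEW_GENUS_CANDIDATE`. These are the quantities `scripts/acceptance.R`
recomputes from scratch, alongside the worked examples from the packaged
population tables.

# Known limitations

* Gene families use nucleotide (not translated) identity; at large
  divergence this undercalls homology relative to protein-level clustering.
* The progressive aligner is intentionally simple (no iterative refinement,
  no consistency scoring); it is adequate for marker genes at the
  divergences simulated here, not a general MSA tool.
* LCB detection requires exact family-set equality across member genomes,
  so heavily mosaic regions fragment into many small blocks rather than few
  long ones with internal variation.
* Cut heights, the 90% identity threshold and the 50% similarity rule are
  conventions taken as user parameters, not quantities the package
  estimates.
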