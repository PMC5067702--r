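---
title: "Associating differentially expressed non-coding RNAs with protein-coding targets by genomic context"
author: "ncontext"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Associating differentially expressed non-coding RNAs with protein-coding targets by genomic context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncontext)
```

## The problem

Most functional annotation of transcriptome data concentrates on
protein-coding genes. Long non-coding RNAs — long intergenic ncRNAs
(lincRNAs), antisense RNAs and transcribed pseudogenes — are routinely
detected on expression platforms but rarely annotated with candidate
regulatory roles, because their mechanisms are poorly catalogued. A
pragmatic, widely used strategy is *contextual annotation*: assign each
differentially expressed ncRNA a set of **putative protein-coding
targets** using genomic context alone, then interrogate those targets
with the well-developed machinery available for coding genes (protein
interaction networks, gene-set over-representation).

`ncontext` implements this strategy as a tested pipeline for two-tissue,
multi-timepoint expression designs (the motivating setting is a rat
sciatic-nerve injury time course with dorsal root ganglion and sciatic
nerve profiled at days 0, 1, 4, 7, 14 in triplicate). The three
association procedures are:

* **lincRNA neighborhood** — every differentially expressed
  protein-coding gene on the same chromosome within a fixed genomic
  window of the lincRNA locus (default ±3 Mb) is a putative cis target,
  ranked closest-first;
* **antisense overlap** — a coding gene is a putative target of an
  antisense RNA iff the two loci overlap on opposite strands of the
  same chromosome;
* **pseudogene parentage** — each pseudogene sequence is locally
  aligned against candidate coding cDNAs and assigned to its best
  unique hit (ties are ambiguous and excluded by default), emulating a
  best-BLAST-hit protocol with the unique-hit filter.

## Differential expression model

Each post-baseline day is contrasted against the day-0 group of the
same tissue (intervals I1..I4 for days 1, 4, 7, 14). Per feature and
contrast the pipeline computes:

* a **signed linear fold change** on group means of linear-scale
  intensities: $r = \bar x_{I}/\bar x_{b}$, reported as $r$ if
  $r \ge 1$ and $-1/r$ otherwise, so $|FC| \ge 1$ and the sign encodes
  direction;
* a **two-sided Welch t-test** on log2 intensities. Welch rather than
  pooled-variance is the default because with $n = 3$ per group
  variance homogeneity cannot be assessed. Group variances are floored
  at `var_floor` (default `1e-8` on the log2 scale) so exact ties give
  $t = 0$, $p = 1$ instead of 0/0 — this matters for noise-free
  simulated data;
* a **Benjamini–Hochberg q-value**, adjusted within each
  (tissue, interval) contrast across all features. Per-contrast
  adjustment matches the per-contrast structure of the reported count
  tables; a global adjustment would couple contrasts of different
  sizes.

A feature is flagged DE when $|FC| > 1.5$ (strict), $p < 0.05$ and
$q < 0.05$. Probe-level results are collapsed to genes by keeping, per
(gene, tissue, interval), the probe with the smallest q (ties: largest
$|FC|$, then probe id); a probe mapped to several genes contributes to
each of them and is reported.

With $n = 3$ per group a Welch test has roughly 4 degrees of freedom,
so even a large, perfectly clean effect cannot produce a p-value much
below $\sim 10^{-4}$. Under heavy multiple-testing burdens the
$q < 0.05$ clause therefore dominates the DE call and moderate effect
sizes are under-called. This is a known property of small-$n$
microarray designs, not of the implementation; users analysing designs
of this shape may prefer moderated statistics (out of scope here) or a
two-stage use of the FDR cutoff.

## Distance, overlap, and boundary conventions

Published tables of neighbor distances rarely define their convention.
`ncontext` uses the **boundary gap**: for non-overlapping intervals the
downstream start minus the upstream end (1-based inclusive
coordinates), so adjacent features have gap 1 and overlapping features
gap 0. The window test is inclusive: a gap of exactly 3,000,000 bp is
retained, 3,000,001 is not. Each association carries a side
(left/right/overlap, from the target's position relative to the
lincRNA) and a megabase bin (≤1 MB / ≤2 MB / ≤3 MB, thirds of the
window), mirroring the layout of published evidence tables. The
alternative start-to-start convention can be emulated by the caller
since all coordinates are exposed, but the boundary gap is the default
because it reproduces the published worked distances exactly (e.g. a
target whose start sits 274,577 bp beyond the lincRNA end is reported
at distance 274,577).

Antisense pairing requires ≥ 1 bp of genomic overlap by default
(`min_overlap`). The alternative reading — opposite-strand proximity
without overlap — is not the standard definition of an antisense
pair, so overlap was chosen; the parameter makes the requirement
stricter if desired.

Chromosome labels are compared as exact strings; `read_gtf()` has a
`normalize_chrom` flag that strips a leading `"chr"`, since Ensembl
GTFs are unprefixed while UCSC-style files are not.

## Alignment and parental assignment

Local alignment uses affine-gap Smith–Waterman scoring with BLASTN-like
defaults: match +2, mismatch −3, gap open 5, gap extend 2 (a gap of
length $k$ costs $5 + 2k$). E-values are not computed; gating is on raw
score (default ≥ 50) and identity over aligned columns (default
≥ 0.7). These defaults retain a pseudogene that diverged from its
parent by ~30% while rejecting alignments between unrelated random
sequences (expected identity 0.25, local score near 0 at these
penalties). Candidates are ranked by score, then identity, then
subject id; only the top hit is kept. When the top two hits tie on both
score and identity across different subjects, the pseudogene is
*ambiguous*: excluded from the unique list and reported separately
(`ambiguous = "first"` keeps the lexicographically first subject
instead). Pre-computed BLAST tabular (outfmt 6) hits can be supplied in
place of the built-in alignment.

## Networks and over-representation

Interaction networks are read from STRING-style edge tables
(`protein1`, `protein2`, `combined_score`); integer scores on the
0–999 scale are divided by 1000, tables already on [0, 1] are detected
by their maximum. Confidence filtering is inclusive at the threshold
(default 0.7, a stringent setting chosen to control false positive
interactions). ncRNA→target links are superimposed as
**association-type edges**, which are exempt from the confidence filter
and excluded from connectivity and path computations — they represent
a different relation (annotation, not interaction), which is also how
published figures draw them (dotted vs solid). Shortest paths use
fewest edges with lexicographic tie-breaking, so results are
deterministic.

Pathway annotation against proprietary knowledge bases is out of
scope; a generic hypergeometric over-representation test against a
user-supplied GMT file is provided instead: $p = P(X \ge k)$ for the
overlap $k$ under sampling without replacement from the background,
BH-adjusted across sets.

## What the simulator emulates

`simulation_config()` defaults encode the motivating design: two
tissues (SN, DRG), days 0/1/4/7/14, three replicates, log-normal
intensities (log2 ~ Normal(8, 1.5)), measurement noise sd 0.25 on the
log2 scale, planted signed log2 effects of magnitude 2. The annotation
generator places features by rejection sampling (deterministic given
the seed, with an explicit placement error rather than silent
truncation when a configuration does not fit) and plants three
recoverable relation classes: lincRNA–neighbor pairs at exact requested
gaps and sides, antisense pairs overlapping by a requested fraction of
the shorter member on opposite strands, and pseudogenes whose cDNA is a
parent copy mutated at per-site substitution/indel rates. Differential
effects are planted on the members of the planted relations,
round-robin across contrasts with alternating sign.

Two generator properties are deliberate design choices rather than
realism:

* **cis isolation** — coding genes destined to carry planted effects
  are placed outside the neighbor window of every lincRNA except their
  own partner. This makes the planted association set *identifiable*:
  on a zero-noise run the pipeline's output equals the truth manifest
  exactly, which is the self-consistency property the recovery tests
  assert. Real genomes offer no such guarantee; on real data the
  neighborhood procedure necessarily reports all windowed DE genes,
  ranked by distance.
* **clean intensities** — no background correction, dye/batch effects,
  spatial artifacts or cross-hybridization are simulated, and by
  default each feature has one probe (`probes_per_feature > 1`
  exercises the collapse rule). Passing recovery tests therefore
  demonstrates correctness of the statistical and interval machinery,
  not robustness to array artifacts.

Problem sizes used by the test suite are kept small on purpose: tens of
features for exactness checks, ~1,000 features for the noisy recovery
run, 100-instance loops for the brute-force oracle comparisons, and
20 pseudogenes × 40 candidates for parental recovery. These sizes give
stable verdicts for the properties being checked while keeping the
suite quick to run; the operations themselves are vectorised
(GenomicRanges interval indexing, vectorised group statistics) and
scale to platform-sized inputs.

## Numerical and degenerate-input choices

* `normalize_log2()` refuses non-positive intensities, naming the
  offending cell; optional per-sample median centering.
* `signed_fold_change()` errors on a zero baseline mean rather than
  returning infinity.
* BH adjustment delegates to `stats::p.adjust(method = "BH")`; the
  package's tests verify it against a literal implementation of the
  step-up formula.
* An empty GTF yields an empty annotation set with a warning (an
  absent file is an error).
* Local alignment of sequences with no positive-scoring block reports
  score 0, length 0, identity `NA` ("no hit") rather than failing.
* Path queries between disconnected endpoints return a "no path"
  result, not an error; unknown endpoints are an error.

## Known limitations

* Trans-acting (distal or other-chromosome) lincRNA targets, RNA–protein
  interaction prediction and miRNA targets are out of scope; the
  procedures annotate *putative* cis targets only, and retained targets
  are candidates, not demonstrated regulatory relationships.
* Cross-species coordinate lifting is not performed: neighbor calls are
  computed within one source's coordinate system, and a secondary
  (e.g. mouse) annotation is merged only for provenance-aware counting.
* The DE module implements the plain FC + t-test + BH protocol; no
  moderated (empirical Bayes) statistics or time-series trend tests.
* STRING's evidence-channel score combination is not reproduced; edge
  tables are consumed as given.

## A worked example

```{r example, eval = FALSE}
library(ncontext)

cfg <- simulation_config(noise_sd_log2 = 0, seed = 7)
res <- run_pipeline(cfg)

# planted relations are recovered exactly on a zero-noise fixture
res$neighbors[, c("ncrna", "target", "distance", "side", "bin", "target_de")]
res$parental[, c("ncrna", "target", "identity")]

# the published worked pairs, reproduced from their fixture
fx <- build_published_fixture()
sn <- fx$pairs[fx$pairs$tissue == "SN", ]
nb <- find_lincrna_neighbors(fx$annotation, sn$lincrna_id,
                             fx$deg_table$feature[fx$deg_table$tissue == "SN"],
                             window = 3e6)
length(unique(nb$target))   # 26
```
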