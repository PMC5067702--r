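# ncontext

Genomic-context target annotation for differentially expressed
non-coding RNAs, with a planted-truth simulator.

## What it does and who it is for

Expression platforms detect long non-coding RNAs — lincRNAs, antisense
RNAs, transcribed pseudogenes — but give no hint of what they regulate.
`ncontext` is for transcriptomics analysts who want to carry those
detections forward: it assigns each differentially expressed ncRNA a
set of *putative protein-coding targets* from genomic context alone,
and then lets the targets be studied with standard coding-gene tooling
(protein-interaction subnetworks, gene-set over-representation). The
motivating setting is a two-tissue, five-timepoint nerve-injury
microarray time course (dorsal root ganglion and sciatic nerve at days
0, 1, 4, 7, 14, three replicates), but any design with per-tissue
baselines fits.

## The method

**Differential expression.** Each post-baseline day is contrasted
against day 0 within a tissue (intervals I1..I4). Per feature: signed
linear fold change FC (ratio of linear-scale group means, sign =
direction, |FC| ≥ 1), two-sided Welch t-test on log2 intensities, and
Benjamini–Hochberg q within each contrast. DE ⇔ |FC| > 1.5 ∧ p < 0.05
∧ q < 0.05. Probes collapse to genes by minimum q (ties: largest |FC|,
then probe id).

**Contextual targets.** Three relations, each intersected with DE
status:

| relation   | rule                                                                    |
|------------|-------------------------------------------------------------------------|
| neighbor   | DE coding gene within ±3 Mb boundary gap of a lincRNA locus (inclusive), closest first, with side and megabase bin |
| antisense  | coding gene overlapping an asRNA on the opposite strand of the same chromosome (≥ 1 bp) |
| parental   | best unique local-alignment hit of a pseudogene cDNA against coding cDNAs (Smith–Waterman, match +2 / mismatch −3 / gap 5+2k; score ≥ 50, identity ≥ 0.7; ties → ambiguous, excluded) |

**Networks and enrichment.** STRING-style edge tables filtered at
combined score ≥ 0.7; ncRNA→target links superimposed as
association-type edges (exempt from the filter, excluded from
connectivity); components and deterministic shortest paths; generic
hypergeometric over-representation against a user GMT.

**Simulator.** `simulation_config()` / `simulate_dataset()` generate an
annotation with planted neighbor/antisense/parent relations, cDNA
sequences in which each pseudogene is a mutated parent copy, and a
log-normal intensity matrix with planted signed log2 effects — plus a
truth manifest, so the whole pipeline is testable with no downloads.

## Worked example

```r
library(ncontext)

cfg <- simulation_config(noise_sd_log2 = 0, seed = 7)
res <- run_pipeline(cfg)

res$neighbors[, c("ncrna", "target", "distance", "side", "bin", "target_de")]
#>      ncrna  target distance  side   bin target_de
#> 1 LINC0001 PCG0001   274577 right <=1MB      TRUE
#> 2 LINC0002 PCG0002    50000  left <=1MB      TRUE
#> 3 LINC0003 PCG0003  1500000 right <=2MB      TRUE
#> 4 LINC0004 PCG0004  2500000  left <=3MB      TRUE
#> 5 LINC0005 PCG0005   800000 right <=1MB      TRUE

res$parental[, c("ncrna", "target", "identity")]
#>     ncrna  target  identity
#> 1 PSG0001 PCG0009 0.9249448
#> ...
```

On this zero-noise fixture every planted relation is recovered exactly:
each lincRNA's target is reported at its planted distance and side
(e.g. `PCG0001` at 274,577 bp to the right of `LINC0001`, in the ≤1 MB
bin), every target is DE in its planted contrast (`target_de TRUE`),
and each pseudogene maps back to its parent with the identity implied
by the mutation rate (~0.92–0.96 at the default 5% substitution rate).

A thin CLI over the same functions ships in `inst/cli/ncontext.R`
(`simulate`, `de`, `run` subcommands).

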