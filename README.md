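# rpoNscan

Genome-wide analysis of σ54 (RpoN) dependent transcription from a
three-strain bacterial RNA-seq design, with a ground-truth simulator for
validating every stage.

σ54 is the bacterial enhancer-dependent sigma factor: its holoenzyme binds
−24/−12 promoter elements but stays transcriptionally silent until a
cognate AAA+ ATPase activator remodels the closed complex. Deleting σ54's
N-terminal Region I yields an *activator-bypass* allele that can transcribe
without activation. Comparing expression across three strains — wild-type
*rpoN* (`WT`), the Region-I-deleted bypass allele (`dRI`) and an *rpoN*
deletion (`none`) — separates four regulatory behaviours per gene:
activator (Region I)-dependent activation, low-level bypass transcription,
repression *by* σ54 (e.g. through promoter occlusion of an overlapping σ70
promoter), and no σ54 involvement. The package implements that analysis for
users who want to run it on per-gene count tables or to study its
statistical behaviour on simulated genomes with known truth.

## What it computes

- **RPKM**: `count × 10⁹ / (gene_length_bp × library_size)`.
- **MA contrasts** for strain pairs (WT vs none, WT vs dRI, dRI vs none):
  `M = log₂(RPKM₁ + ε) − log₂(RPKM₂ + ε)`,
  `A = ½[log₂(RPKM₁ + ε) + log₂(RPKM₂ + ε)]`, with pseudocount ε = 0.5
  RPKM inside the logs only. `|M| ≤ 2` is the four-fold band of an MA plot.
- **One-way ANOVA** per gene across the three strains on log₂(RPKM + ε),
  with Benjamini–Hochberg q-values.
- **Gene categorisation** by a fixed decision ladder: `RI_dependent`
  (M(WT,dRI) ≥ 2 and M(WT,none) ≥ 2), else `bypass` (M(dRI,none) ≥ 1),
  else `sigma54_repressed` (−M(WT,none) ≥ 2 and −M(dRI,none) ≥ 2), else
  `unchanged`; significant q required for the first three when replicates
  exist.
- **Promoter motif scanning**: weighted-mismatch consensus search for the
  σ54 −24/−12 motif (`TGGCACG … N₄₋₅ … TTGCW`, invariant GG/GC positions
  weighted 2) and the σ70 −35/−10 motif (`TTGACA … N₁₆₋₁₈ … TATAAT`), both
  strands, plus the fraction of sites conserving the repression-critical C
  of the −12 GC element.
- **Positional classification** of σ54 sites at σ54-repressed genes
  relative to the active σ70 promoter footprint: class I (overlapping, same
  strand), II (overlapping, opposite strand), III (near, non-overlapping),
  IV (distal/convergent).
- **Synthetic data**: genomes with planted promoters of each type and
  negative-binomial three-strain counts (`var = μ + μ²/k`), written as
  FASTA/GFF3/BED/TSV fixtures with a YAML manifest.

## Worked example

```r
library(rpoNscan)

g  <- build_genome(n_genes = 200,
                   n_planted_per_type = c(sigma54_activator_dependent = 5,
                                          sigma54_bypass = 5,
                                          sigma70_constitutive = 5,
                                          sigma70_repressed_by_sigma54 = 4),
                   seed = 101)
cm <- simulate_counts(g, depth = 1e6, n_replicates = 3, seed = 102)
ex <- quantify_expression(cm, g)
calls <- call_genome(ex)
calls$summary
#>      RI_dependent            bypass sigma54_repressed         unchanged
#>                 4                 3                 4               189

s54 <- scan_motif(g$sequence, sigma54_motif(2))
s70 <- scan_motif(g$sequence, sigma70_motif(0))
byp <- g$promoters[g$promoters$promoter_type == "sigma54_bypass", ]
minus12_conservation(s54[s54$elem1_start %in% byp$elem1_start, ])
#> [1] 0

classify_repressed_set(calls, s54, s70, g)$counts
#>   I  II III  IV
#>   1   1   1   1
```

All four planted repressed genes are recovered and fall into the four
positional classes; bypass promoters are planted with a non-consensus −12
base, so their C conservation is 0 (repressive sites keep it at 1). At this
depth and replication the weaker calls are not certain: here 4 of 5 planted
activator-dependent and 3 of 5 planted bypass genes are recovered — the
two-fold bypass rule and the q ≤ 0.05 gate both cost sensitivity, which is
exactly the behaviour the simulator exists to quantify (see the methods
vignette).

The full pipeline, writing every stage output plus a deterministic run
manifest:

```r
run_pipeline(pipeline_config(seed = 42), outdir = "run42")
```

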