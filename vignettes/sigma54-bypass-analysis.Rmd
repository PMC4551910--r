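---
title: "Methods: three-strain sigma-54 regulon analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-strain sigma-54 regulon analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpoNscan)
```

# The experimental design being modelled

σ54 (RpoN) promoters are recognised by conserved −24 (`TGGCACG`-like) and
−12 (`TTGC`-like) elements, but the σ54 holoenzyme cannot melt promoter DNA
on its own: its Region I occludes the DNA entry channel until a cognate
AAA+ activator remodels the complex. A Region-I-deleted allele (here `dRI`)
bypasses that requirement at some promoters. A three-strain expression
comparison — wild-type *rpoN* (`WT`), bypass allele (`dRI`), *rpoN*
deletion (`none`) — therefore carries a clean logic:

* genes needing both σ54 and its activator machinery are high only in `WT`;
* genes transcribed by the bypass holoenzyme without activation are higher
  in `dRI` than in `none` (typically at low level);
* genes repressed by σ54 occupancy (for instance where a σ54 site overlaps
  an active σ70 −35/−10 promoter and the silent σ54 holoenzyme occludes it)
  are highest in `none`.

The package turns that logic into a reproducible pipeline operating on
per-gene counts, and pairs it with a simulator that plants each promoter
type with known truth so every stage can be validated quantitatively.

# Quantification

Counts are normalised to RPKM, `count × 10⁹ / (length_bp × library_size)`,
with the library size taken as the column sum of the count table. Pairwise
strain contrasts use MA statistics computed on per-strain mean RPKM:

$$M = \log_2(\mathrm{RPKM}_1 + \varepsilon) - \log_2(\mathrm{RPKM}_2 +
\varepsilon), \qquad A = \tfrac12\left[\log_2(\mathrm{RPKM}_1 +
\varepsilon) + \log_2(\mathrm{RPKM}_2 + \varepsilon)\right].$$

The pseudocount ε (default 0.5 RPKM) lives **inside the logs only**; RPKM
values are reported unshifted. It keeps M finite for genes with zero
counts, and because the same ε is used everywhere the three contrasts obey
the exact identity `M(WT,none) = M(WT,dRI) + M(dRI,none)` and M is
anti-symmetric under swapping strains. `|M| ≤ 2` is the conventional
four-fold band of an MA plot; the boundary value `M = 2` is defined to sit
*inside* the band (`export_ma_plot_data()` flags only `|M| > 2`), a
semantics the acceptance checks exercise in the ε → 0 limit.

With at least two replicates per strain, each gene gets a classical
equal-variance one-way ANOVA across the three strains on
`log₂(RPKM + ε)` — F = MS_between/MS_within with (2, N − 3) degrees of
freedom — and Benjamini–Hochberg q-values. We chose the classical rather
than Welch form as the simplest reading of "one-way ANOVA", and the log
scale because variance is closer to constant there for overdispersed
counts. With a single replicate per strain the F/p/q columns are flagged
not computable rather than fabricated, and downstream calling runs on M
values alone.

Degenerate inputs are handled explicitly: all group means equal gives
F = 0, p = 1; zero within-group variance with unequal means gives F = ∞,
p = 0.

# Gene categorisation

`classify_gene()` is a fixed-precedence ladder with two thresholds:

1. `RI_dependent` — `M(WT,dRI) ≥ t_major` **and** `M(WT,none) ≥ t_major`;
2. `bypass` — `M(dRI,none) ≥ t_bypass`;
3. `sigma54_repressed` — `−M(WT,none) ≥ t_major` and
   `−M(dRI,none) ≥ t_major`;
4. `unchanged` otherwise.

`t_major = 2` (four-fold) matches the MA-plot band; `t_bypass = 1`
(two-fold) is deliberately smaller because bypass transcription is a
low-level phenomenon — a full four-fold requirement would define it away.
When q-values exist, rules 1–3 additionally require `q ≤ alpha` (default
0.05); genes failing the gate fall to `unchanged`. The precedence order
resolves rare genes satisfying several rules in favour of the stronger
activator-dependent call, mirroring the sequential scoring logic of the
strain comparisons. All three thresholds are arguments and are recorded in
the call output.

Raising either threshold can only shrink the non-`unchanged` categories
(monotonicity), and the calls are a pure per-gene function of the
statistics, so permuting input order permutes output identically — both
properties are asserted in the test suite.

# Motif models and scanning

The σ54 model is two consensus elements, `TGGCACG` (−24 region) and
`TTGCW` (−12 region), separated by a 4–5 nt spacer. Scoring is weighted
mismatch counting: the invariant GG of the −24 element and GC of the −12
element carry weight 2, all other positions weight 1, and a site is
reported when the total weighted mismatches are at most the threshold
(default 2). The σ70 model is `TTGACA`/`TATAAT` with a 16–18 nt spacer,
uniform weights, default threshold 3. These are declared, configurable
operationalisations of the canonical consensus descriptions — no published
position weight matrix is implied. Degenerate IUPAC letters in a consensus
match every base of their set at zero cost; an `N` in the scanned sequence
never matches anything.

Scanning covers both strands; minus-strand hits are reported in plus-strand
coordinates. Transcription start sites are inferred by convention: the σ54
tss is 12 nt downstream of the −12 C consensus position (the C of `TTGC`),
the σ70 tss 7 nt downstream of the −10 element start. These offsets are
package conventions chosen to be consistent between the simulator and the
scanner, not measured values.

`minus12_conservation()` reports the fraction of σ54 sites carrying the
consensus C at the −12 GC position — the position implicated in keeping
basal (activator-independent) transcription in check, and therefore the
position expected to be degraded at bypass-permissive promoters and intact
at repressive ones. `build_consensus()` aligns sites on their concatenated
elements (the variable spacer is dropped), giving equal-width inputs; a
column's consensus letter is the majority base at frequency ≥ 0.75,
otherwise the IUPAC code covering all bases at frequency ≥ 0.25.

Site-to-gene assignment places a site's inferred tss in a window around the
gene's 5′ end (defaults 300 bp upstream, 100 bp downstream, measured along
the gene's orientation); the nearest gene wins, with residual ties going to
the smaller start coordinate. Site strand is deliberately not required to
match the gene: repressive σ54 sites can sit on either strand.

# Positional classes of repressive sites

For genes called `sigma54_repressed`, the σ54 site is positioned relative
to the likely σ70 RNA-polymerase footprint, taken as the interval from 5 bp
upstream of the −35 element to 20 bp downstream of the tss (pads
configurable). Classes are:

* **I** — σ54 element span overlaps the footprint, same strand: direct
  occlusion of the promoter;
* **II** — overlaps on the opposite strand;
* **III** — no overlap but within `distal_cutoff` (default 100 bp);
* **IV** — farther than the cutoff, the distal/convergent configuration in
  which repression plausibly arises from interference between convergent
  transcription rather than promoter occlusion.

The exact geometric feature separating overlapping same-strand from
opposite-strand arrangements, and near from distal ones, is not recoverable
from qualitative class descriptions, so strand and proximity are the
declared operationalisation here; all parameters are recorded in the output
metadata. For this step the assignment windows default wider (400 bp
upstream, 300 bp downstream) so that distal class IV sites inside the gene
body are still attributed to their gene. When a gene has several σ54 or σ70
sites the best-scoring one is used; genes missing either site type are
reported as unclassifiable rather than silently dropped. Classification is
invariant under coordinate translation and under reverse-complementing the
genome, and per-class consensus motifs are built once a class has at least
two members.

# The synthetic-data generator

`build_genome()` lays out non-overlapping genes (lengths uniform on
400–1500 bp, intergenic gaps 200–300 bp — wide enough that no two planted
element sets can collide) on an i.i.d. background at configurable GC
(default 0.50), then writes promoter elements verbatim:

* activator-dependent σ54 promoters: consensus elements, −12 base C,
  strain activities (WT, dRI, none) = (8, 1, 1);
* bypass σ54 promoters: identical except the −12 C is replaced by A and
  activities (8, 2.5, 1) — low-level activator-independent output;
* constitutive σ70 promoters: `TTGACA`/`TATAAT`, activities (1, 1, 1);
* repressed σ70 promoters: activities (1, 1, 8), plus a consensus-C σ54
  site placed per requested positional class (I/II just downstream of the
  tss inside the footprint on the same/opposite strand, III ~30 bp upstream
  of the footprint, IV on the opposite strand 150 bp into the gene body).

The 8-fold activation/repression magnitude is a typical strong regulon
effect; the 2.5-fold bypass magnitude encodes "low level" — no printed
effect sizes exist for these, so they are stated assumptions, configurable
in `sim_params()`. Any background window that spuriously contains a
zero-mismatch σ54 or σ70 consensus core is rejection-resampled, so the
truth table is exhaustive and recovery tests can be exact. Identical
`(params, seed)` give byte-identical genomes.

`simulate_counts()` draws negative-binomial counts with mean
`μ(g, strain) = depth × length_kb(g) × activity(g, strain) / normaliser`,
the per-strain normaliser being `Σ_g length_kb × activity`, so each
strain's expected total equals `depth` exactly (sequencing yields
near-equal totals per sample). Variance follows `μ + μ²/k` with shared
dispersion `k` (default 10). One consequence worth knowing: because each
strain is normalised to the same total, planting strong effects shifts
*relative* expression of every other gene slightly, and the realised
count-ratio of a planted effect is its activity ratio scaled by the
normaliser ratio — on small genomes with several 8-fold promoters this
dilution is material, which is why the class-exemplar fixture in the
acceptance checks uses a 160-gene genome rather than a minimal one.

What the generator does **not** emulate: operon structure, read-level
artefacts (rRNA depletion, library chemistry, mapping ambiguity),
correlated biological replicates, condition-dependent activity, or any
activator identity. Passing recovery tests therefore demonstrates that the
statistical machinery behaves as designed under its stated model, not that
real libraries meet that model.

# Reference study conditions and test sizes

The defaults of `pipeline_config()` are the package's reference
conditions: 500 genes, 10 planted promoters per type, 3 replicates per
strain at 2×10⁶ expected reads, dispersion 10, seed 42 for the genome and
43 for the counts. The test suite additionally uses: a 2000-gene
all-constitutive simulation for null calibration of the ANOVA (the
fraction of genes at p < 0.05 should sit near 0.05); 100 random 5 kb
sequences across thresholds 0–4 for scanner-versus-enumerator equivalence;
and small 12–300 gene genomes for fixture round-trips, null calling and
class geometry.
These sizes were chosen to make Monte-Carlo error small relative to the
assertions while keeping a full test run in a few minutes on one core.

# Numerical and interface choices

* Coordinates are 1-based inclusive internally — the R/Bioconductor
  (IRanges/GRanges) convention — with GFF3 written 1-based and BED written
  0-based half-open by rtracklayer.
* Determinism: every stochastic function takes an explicit seed;
  `run_pipeline()` writes a manifest with a config hash and per-file MD5
  checksums, and identical configurations produce byte-identical outputs.
* Standard formats go through Biostrings (FASTA) and
  rtracklayer/GenomicRanges (GFF3, BED); YAML through the yaml package; the
  BH adjustment is `stats::p.adjust`. The motif scanner, consensus builder,
  classifiers and the vectorised ANOVA sums of squares are implemented in
  the package, and the test suite checks the scanner against an independent
  brute-force enumerator and the ANOVA against `stats::oneway.test`.
* Tie-breaks are documented and deterministic: nearest gene then smaller
  start coordinate for site assignment; best score then scan order for
  site selection.

# Known limitations

* **Sensitivity at the reference conditions.** With dispersion 10 and 3
  replicates, sd(M) ≈ 0.37; the bypass rule's margin (true M ≈ 1.4–1.5
  against a two-fold threshold) and, more severely, the q ≤ 0.05 gate on a
  per-gene ANOVA with 6 denominator degrees of freedom leave bypass
  recovery well below the recovery of the 8-fold activator-dependent and
  repressed classes. The acceptance script reports these sensitivities
  honestly; raising replication or dispersion, or relaxing the gate, are
  the levers a study design would use.
* The ANOVA assumes equal variances and near-normal log-scale noise; its
  null calibration is verified by simulation, not guaranteed analytically.
* The class I–IV geometry is a declared operationalisation; real promoter
  architectures are more varied than strand plus proximity.
* RPKM with total-count normalisation couples genes through the library
  size; no DESeq-style size factors are attempted, by design.
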