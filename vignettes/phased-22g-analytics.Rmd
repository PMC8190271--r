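---
title: "Phased 22G-RNA biogenesis analytics: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phased 22G-RNA biogenesis analytics: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

In the *C. elegans* germline, Argonaute-bound 22G-RNAs — ~22-nt antisense
small RNAs with a 5' guanosine — are synthesized by an RNA-dependent RNA
polymerase (RdRP) using mRNAs as templates. `phase22g` implements the
computational side of a model in which target slicing primes RdRP synthesis
*on translating mRNAs*: 22G-RNA 5' ends sit in a fixed register with
ribosome-protected fragments (RPFs), cleavage concentrates immediately
downstream of ribosomes stalled at non-optimal codons, and codon optimality
(and with it translation efficiency, TE) antagonizes 22G-RNA production.

The package provides, as reusable functions:

* small-RNA classification (`classify_small_rna`) with the poly-U rescue
  path (`rescue_polyU`): unmapped reads matching *G + 20–25 nt + ≥1
  trailing T* have the whole 3' T-run trimmed and the core remapped;
* RPF selection (28–30 nt, sense, 5' end in the CDS) and A/P-site codon
  assignment for 29-mers at read positions 13–15 (P) and 16–18 (A);
* TE as the ratio of Ribo-seq to RNA-seq TPM, with the cumulative bins
  log2TE ≥ 3, ≥ 2, ≥ 1, ≤ −1, ≤ −2, ≤ −3 and a neutral band |log2TE| ≤ 0.1;
* the RPF/22G distance distribution over offsets −120…+120, its population
  z-scores, the Fourier periodogram with dominant-period detection, and
  A/P-optimality-stratified peak calling in the (−15, 45) reporting range;
* pooled RSCU, differential RSCU against neutral-TE genes, optimal /
  non-optimal codon calling, wobble-adjusted tRNA decoding capacity, and
  synonymous whole-CDS optimization;
* IP-over-input target calling (RPM ≥ 1 and enrichment ≥ 2 in every
  replicate), abundance bins [1,50), [50,150), [150,∞), exact
  hypergeometric overlap statistics, and TSS→TES metaprofiles.

Because the real study's libraries are not reproducible at desk scale, the
package ships a seeded generator (`sim_config`, `simulate_*`) that plants
every statistical structure the analyses assume, so each stage is testable
end to end against known truth.

## The synthetic study

One synthetic chromosome carries `n_genes` protein-coding genes (default
200) and 10 structural decoys (rRNA/tRNA/sn(o)RNA/ncRNA). Each CDS is
ATG + internal codons + stop; internal codons are drawn per gene from
planted optimal/non-optimal codon sets with a per-gene optimality fraction
θ ~ Uniform(0,1). 3'UTRs are 100–300 random nt. mRNA abundance is
log-normal (meanlog 4, sdlog 1) — a right-skewed expression distribution
spanning ~3 orders of magnitude, as in real transcriptomes.

**Planted codon sets.** For every multi-codon amino-acid family one codon
is optimal and one non-optimal, alternating which end of the sorted family
is chosen from one amino acid to the next. The alternation balances
third-position base composition between the two sets, so codon optimality
is statistically decoupled from local base content — in particular from the
template cytosines where an RdRP can initiate. Without this, optimality
and C-site placement would be confounded by construction, and sequence
composition could masquerade as (or mask) ribosome phasing.

**Ribosome footprints.** Per-gene footprint counts are proportional to
abundance × TE × CDS codon count; the length factor is required for the
TPM-ratio estimator (which divides by CDS length) to recover the planted
per-codon TE. Within a gene, the P-site codon index is sampled with weight
`dwell_nonoptimal` (default 4) when the A- or P-site codon is non-optimal,
else 1 — ribosome stalling at non-optimal codons. The planted TE is
(mean dwell weight per codon)^−1, normalized to mean 1 across genes; its
log2 range is therefore about ±1, which is why the synthetic codon-usage
analyses bin "highly translated" genes at log2TE ≥ 1 (the ≥ 2 and ≥ 3
cumulative bins are empty at this dwell ratio; the bin is a parameter and
the ≥ 3 default of the real-data procedure is kept for real-scale inputs).
The footprint 5' end is placed 12 nt upstream of the P codon start — read
nts 13–15 cover the P codon, 16–18 the A codon — plus a digestion jitter
of −2…+2 nt (50% exactly in frame). The jitter mirrors the nuclease
trimming heterogeneity of real ribosome profiling and matters beyond
realism: with perfectly codon-registered 5' ends, every placement
fluctuation of 22G ends is coherent within one mod-3 residue class of the
distance histogram, so the period-3 band carries excess variance at any
scale and an unphased control could never look clean. Out-of-frame
footprints are exactly the records the A/P assignment flags and excludes,
as in the real pipeline.

**22G-RNAs.** Antisense reads of 21–23 nt whose 5' nucleotide is G
(template C). With probability `p_phased` (default 0.8) the 5' end is
placed at the ribosome's downstream boundary — 29 nt past the in-frame
footprint start of a footprint sampled from the gene's Ribo-seq library,
restricted to stalled footprints (`phased_from_stalled`, default on),
because cleavage is positioned by the ribosome itself, not by where the
nuclease happened to trim the sequenced footprint. Otherwise the 5' end is
drawn from background template-C sites (20% in the 3'UTR), with the
reading-frame residue drawn uniformly *before* choosing a site within it
and with exact (not multinomial) allocation across residues: both choices
remove sampling noise that is coherent along residue classes of the
distance histogram and would otherwise surface as spurious period-3 power
in the `p_phased = 0` null.

**Poly-U tails.** With probability `p_polyU` (default 0.2) a non-templated
3' T-run (lengths 1–5, decreasing probabilities) is appended in the FASTQ
output only; the read TSV always stores the templated core. Tails are
planted only at unambiguous sites: the first tail T must mismatch the
template (else the read would still map full-length under exact matching)
and the core must not itself end in T (a tail abutting a templated U-run
has no identifiable boundary under maximal trimming — no method could
recover it). Under these conditions the rescue path recovers essentially
all planted tails, which is what the recovery test asserts.

**IP libraries.** Two IP replicates multiply the per-gene sampling weight
by `ip_enrichment` (default 8) for a planted 5% of genes. After RPM
normalization the realized IP/input ratio is 8 divided by the relative
total-weight inflation of the IP library, so with a small target fraction
it lands well above the 2-fold calling floor while non-targets land well
below it.

**What the generator does not emulate** — and what passing tests therefore
do not show about real data: sequencing errors, PCR duplicates and UMIs,
introns and isoforms, 5'UTRs, multi-mapping ambiguity beyond exact
duplicates, non-uniform RNase preferences, composition-dependent ligation
bias, and the genuine codon-usage diversity of a real genome (each
synthetic gene uses two codons per amino-acid family). Results on this
generator validate the *implementations*; biological conclusions still
require real libraries.

## Numerical and procedural choices

* Coordinates are 0-based half-open internally; GFF3 I/O converts to/from
  1-based inclusive at the boundary, BED-style read TSVs stay 0-based.
  An antisense read's transcript position is that of its own 5'
  nucleotide — the mRNA-downstream edge of its span — which is what makes
  the cleavage register appear at +footprint-length.
* Pairing in the distance histogram is restricted to reads on the same
  gene; counts are pooled across genes before z-scoring (the aggregate
  series is what gets z-scored, not per-gene series averaged).
* z-scores use the population (ddof = 0) convention of
  `scipy.stats.zscore`.
* The periodogram is the squared-magnitude DFT over the full ±120 window
  (241 points); the (−15, 45) range is for reporting peaks only. Periods
  are N/k, so the bin nearest 3 nt is 241/80 ≈ 3.0125. Dominance is
  searched among periods 2–12 nt (DC excluded); exact power ties resolve
  to the smaller period.
* TE uses CDS length as the effective length for Ribo-seq TPM and
  transcript length for RNA-seq TPM, computed over non-structural genes
  only; genes under 1 mRNA TPM are excluded (unstable ratios). TE bins
  are cumulative as written (a log2TE = 3.5 gene is in ≥ 1, ≥ 2, ≥ 3);
  disjoint bins are available via `cumulative = FALSE`.
* RSCU pools codon counts across the gene set (per-gene averaging is an
  option); differential RSCU uses a pseudovalue eps = 0.01 against zero
  RSCU; the optimality call threshold is ±0.1 log2 units. Stop codons are
  excluded from RSCU and left unchanged by the optimizer.
* Wobble rules default to G34:U3, U34:G3, and A34-as-inosine (U3/C3/A3)
  on top of Watson–Crick; a Watson–Crick-only mode supports the
  unadjusted comparison. The rule table is fully configurable.
* Target enrichment guards zero input with eps = 0.25 RPM; abundance bins
  are half-open on mean IP RPM. Pooled or per-replicate inputs are both
  supported.
* The toy mapper requires a unique exact full-length match across both
  strands of the transcriptome; ties are dropped. It stands in for a real
  aligner only on synthetic data.
* The poly-U rescue core bound (21–26 nt including the leading G) is
  enforced before remapping; the post-trim 22G window (21–23 nt,
  configurable) is applied after, mirroring the two separately stated
  filters.

## Problem sizes

The test suite and the acceptance script run the full default study
(200 genes, 150k Ribo-seq / 80k small-RNA reads) for the two headline
phasing checks — about 25–45 million counted pairs — and scaled-down
instances (40–100 genes, 10k–60k reads) for recovery, oracle, and
Monte-Carlo suites; these sizes are the package's chosen study conditions
and leave every planted signal detectable with wide margins.

## Known limitations

* The exact-match mapper cannot express mismatches or indels, so the
  rescue path's "initially unmapped" set is exactly the tailed reads; with
  a real aligner the set would also contain error-bearing reads.
* Dominant-period detection reports the discrete N/k grid; with the fixed
  ±120 window the 3-nt register appears as 3.0125.
* The stratified cleavage peak is a z-score maximum; at very small
  simulation scales single high-abundance genes can dominate the pair
  counts and shift the maximum by one codon. The default 200-gene scale
  averages this out.
* `run_pipeline` orchestrates the synthetic walkthrough only; applying the
  functions to real data means building the read TSVs from aligned BAMs
  upstream (outside this package's scope).

## A worked run

```{r}
library(phase22g)
res <- run_pipeline(list(sim = list(seed = 7L)), outdir = "results/run7")
str(res$summary)
```

The `analysis/` directory of the source repository holds the same
walkthrough as six narrated stages (simulate → classify → TE → phasing →
codon optimality → targets), each writing its tables under `results/`.
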