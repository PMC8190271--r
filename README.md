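# phase22g

Analytics for ribosome-phased 22G-RNA biogenesis, with a synthetic study
generator that makes every stage testable end to end.

## The problem

In the *C. elegans* germline, ~22-nt antisense small RNAs with a 5'
guanosine ("22G-RNAs") are made by an RNA-dependent RNA polymerase using
mRNAs as templates and loaded onto the Argonaute CSR-1. A mechanistic
model places their synthesis on *translating* mRNAs: target slicing primes
the RdRP immediately downstream of ribosomes, so 22G-RNA 5' ends fall in a
fixed register with ribosome-protected fragments (RPFs) — a 3-nt
periodicity in the distance between RPF 5' starts and 22G 5' ends, with a
cleavage peak at the 29th position downstream of 29-nt footprints whose A-
and P-site codons are non-optimal — while codon optimality (high
translation efficiency, TE) antagonizes 22G production.

`phase22g` implements the computational procedures this model rests on,
for researchers analyzing matched Ribo-seq / RNA-seq / small-RNA
(IP + input) libraries:

* **Small RNA classification** — `G22` calls (5' G, 21–23 nt, antisense to
  a protein-coding gene) and the **poly-U rescue** path: initially
  unmapped reads matching *G + 20–25 nt + ≥1 trailing T* are T-trimmed,
  remapped, and labelled `G22_polyU`.
* **Ribosome profiling** — 28–30-nt sense-CDS footprint selection; for
  29-mers, P-site = read nts 13–15 and A-site = nts 16–18, with
  codon-optimality flags; TE = Ribo-seq TPM / RNA-seq TPM with cumulative
  bins log2TE ≥ 3, ≥ 2, ≥ 1, ≤ −1, ≤ −2, ≤ −3 (neutral: |log2TE| ≤ 0.1).
* **Phasing** — the distance histogram `d = tpos5(22G) − tpos5(RPF)` over
  ±120 nt pooled within genes, population z-scores, the squared-magnitude
  Fourier periodogram (periods N/k), dominant-period detection over 2–12
  nt, and A/P-optimality-stratified peaks in the (−15, 45) range.
* **Codon usage** — pooled RSCU (`rscu_c = n_a X_c / Σ X`), differential
  RSCU vs neutral-TE genes, optimal/non-optimal codon calling,
  wobble-adjusted tRNA decoding capacity (G34:U3, U34:G3, A34-as-inosine),
  and synonymous whole-CDS optimization.
* **Target calling** — IP over input ≥ 2-fold and RPM ≥ 1 in every
  replicate (RPM = reads per million non-structural mappers), abundance
  bins [1,50), [50,150), [150,∞) RPM, exact hypergeometric overlap
  statistics, and TSS→TES metaprofiles.
* **Synthetic data** — `sim_config()` / `simulate_all()` generate a seeded
  genome, annotation, truth table, and all four library types with planted
  codon optimality, codon-dependent ribosome dwell, cleavage phasing,
  poly-U tailing, and IP enrichment.

## Worked example

```r
library(phase22g)
res <- run_pipeline(list(sim = list(n_genes = 100L,
                                    n_riboseq_reads = 60000L,
                                    n_rnaseq_reads = 40000L,
                                    n_srna_reads = 30000L,
                                    seed = 101L)))
str(res$summary)
```

prints (abridged):

```
dominant_period    : 3.0125
max_z_offset       : z = 6.53 at offset +29
strata$non_optimal : peak +29, z = 4.97
strata$optimal     : peak z = 2.09 (no offset above 3)
te_spearman        : 0.928
codon_jaccard_*    : 1.00 / 1.00
target_sensitivity : 1.00   target_fdr: 0
rescue_stats       : 2361 of 2361 tailed reads rescued
```

Reading the numbers: the periodogram's dominant period is the FFT bin
nearest 3 nt (241/80 = 3.0125) — the ribosome's codon step imprinted on
22G 5' ends; the z-scored distance distribution for non-optimal-A/P 29-nt
footprints peaks at +29 nt (cleavage immediately 3' of the stalled
ribosome) while optimal-site footprints show no comparable peak; estimated
TE recovers the planted per-codon efficiency (Spearman 0.93); differential
RSCU recovers the planted optimal/non-optimal codon sets exactly; and
target calling recovers the planted IP-enriched genes with no false
positives.

The same walkthrough is available as six narrated stages under
`analysis/` (simulate → small-RNA classification → TE → phasing → codon
optimality → target calling), each writing its tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_classify_smallrna.R
# ... through 06_target_calling.R
```

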