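#!/usr/bin/env Rscript

# Stage 5 — codon-usage analytics: pooled RSCU per TE bin, differential
# RSCU against the neutral-TE genes, optimal/non-optimal codon calling
# (scored against the planted sets), wobble-adjusted decoding capacity
# for a synthetic tRNA table, and whole-CDS synonymous optimization of
# the strongest 22G target gene.

source("analysis/00_config.R")

inp <- read_sim_inputs()
te <- read.delim(file.path(RESDIR, "te_table.tsv"))

cds_of <- function(ids) vapply(ids, function(g)
  substr(inp$genes[[g]]$tx_seq, 1L, inp$genes[[g]]$cds_len), character(1))

## differential RSCU: highly translated bin vs neutral TE
hi <- te$gene_id[te$ge1]
neutral <- te$gene_id[te$neutral]
cat(sprintf("TE bins: %d highly translated (log2TE >= 1), %d neutral\n",
            length(hi), length(neutral)))
d <- delta_rscu(rscu(cds_of(hi)), rscu(cds_of(neutral)))
calls <- call_optimal_codons(d)
write.table(d, file.path(RESDIR, "delta_rscu.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

planted <- planted_codon_sets()
jacc <- function(a, b) length(intersect(a, b)) / length(union(a, b))
cat(sprintf("called %d optimal / %d non-optimal codons\n",
            length(calls$optimal), length(calls$non_optimal)))
cat(sprintf("Jaccard vs planted sets: optimal %.2f, non-optimal %.2f\n",
            jacc(calls$optimal, planted$optimal),
            jacc(calls$non_optimal, planted$non_optimal)))

## decoding capacity under wobble rules for a synthetic tRNA table:
## one Watson-Crick tRNA per called optimal codon, abundance graded
trna <- data.frame(anticodon = revcomp(calls$optimal),
                   abundance = round(seq(20, 5,
                                         length.out = length(calls$optimal))))
cap <- decoding_capacity(trna)
cap_wc <- decoding_capacity(trna, wobble_rules(FALSE))
write.table(data.frame(codon = names(cap), adjusted = as.numeric(cap),
                       watson_crick = as.numeric(cap_wc)),
            file.path(RESDIR, "decoding_capacity.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("codons decodable: %d wobble-adjusted vs %d Watson-Crick only\n",
            sum(cap > 0), sum(cap_wc > 0)))

## synonymous optimization of the top planted target (cf. a kinesin
## transgene recoded codon-by-codon): protein unchanged, all sense
## codons replaced by their amino acid's top-RSCU codon
targets <- inp$truth$gene_id[inp$truth$is_target]
top <- targets[1L]
ranking <- codon_ranking(rscu(cds_of(hi)))
native <- cds_of(top)
optimized <- optimize_cds(native, ranking)
stopifnot(identical(translate_cds(native), translate_cds(optimized)))
changed <- mean(codon_split(native) != codon_split(optimized))
cat(sprintf("optimized CDS of %s: %.0f%% of codons replaced, protein identical\n",
            top, 100 * changed))
Biostrings::writeXStringSet(
  Biostrings::DNAStringSet(setNames(optimized, paste0(top, "_optimized"))),
  file.path(RESDIR, "optimized_cds.fa"))
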