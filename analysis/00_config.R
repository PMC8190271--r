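# Shared study conditions for the analysis walkthrough.
#
# A mid-sized instance of the default study conditions: 100 genes and
# moderate library depths keep every driver under ~30 s while leaving
# all planted signals comfortably detectable.

suppressMessages(library(phase22g))

walkthrough_config <- function(seed = 101L) {
  sim_config(n_genes = 100L,
             n_riboseq_reads = 60000L,
             n_rnaseq_reads = 40000L,
             n_srna_reads = 30000L,
             seed = seed)
}

SIMDIR <- "results/simdata"
RESDIR <- "results"
dir.create(RESDIR, showWarnings = FALSE, recursive = TRUE)

read_sim_inputs <- function() {
  genome <- as.character(Biostrings::readDNAStringSet(
    file.path(SIMDIR, "genome.fa")))
  genes <- attach_tx_seq(read_annotation(file.path(SIMDIR, "genes.gff3")),
                         genome)
  truth <- read.delim(file.path(SIMDIR, "truth.tsv"))
  list(genome = genome, genes = genes, truth = truth)
}
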