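# Fixtures built in code: a deterministic toy gene pair and one cached
# small-scale simulation shared across test files.

## plus-strand gene: CDS [100, 400), 3'UTR [400, 500) on chr1
toy_plus_gene <- function(seed = 11) {
  set.seed(seed)
  cds <- paste0("ATG",
                paste(sample(setdiff(names(Biostrings::GENETIC_CODE)
                                     [Biostrings::GENETIC_CODE != "*"],
                                     character(0)), 98, replace = TRUE),
                      collapse = ""), "TAA")
  utr <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
               collapse = "")
  gene_model("gA", "chr1", "+", matrix(c(100L, 400L), ncol = 2),
             c(400L, 500L), "protein_coding", paste0(cds, utr))
}

## minus-strand gene: 3'UTR [600, 700), CDS [700, 1000)
toy_minus_gene <- function(seed = 12) {
  set.seed(seed)
  cds <- paste0("ATG",
                paste(sample(names(Biostrings::GENETIC_CODE)
                             [Biostrings::GENETIC_CODE != "*"],
                             98, replace = TRUE), collapse = ""), "TGA")
  utr <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
               collapse = "")
  gene_model("gB", "chr1", "-", matrix(c(700L, 1000L), ncol = 2),
             c(600L, 700L), "protein_coding", paste0(cds, utr))
}

toy_read <- function(read_id, start, end, strand, seq = NULL,
                     chrom = "chr1", library_id = "lib") {
  if (is.null(seq))
    seq <- strrep("A", end - start)
  data.frame(read_id = read_id, chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand, sequence = seq,
             library_id = library_id, stringsAsFactors = FALSE)
}

small_cfg <- function(...) {
  sim_config(n_genes = 60L, n_riboseq_reads = 40000L,
             n_rnaseq_reads = 30000L, n_srna_reads = 20000L,
             seed = 42L, ...)
}

.shared <- new.env(parent = emptyenv())

## one small full-pipeline run reused by several test files
shared_run <- function() {
  if (is.null(.shared$run))
    .shared$run <- suppressMessages(
      run_pipeline(list(sim = unclass(small_cfg()))))
  .shared$run
}

shared_libs <- function() shared_run()$libs
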