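# Synthetic-data generator: determinism, planted structure, recovery.

test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 12L, n_structural_genes = 3L, seed = 5L)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$truth, s2$truth)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_annotation(s1$genes, p1); write_annotation(s2$genes, p2)
  expect_identical(readLines(p1), readLines(p2))
  r1 <- simulate_riboseq(s1, 2000L)
  r2 <- simulate_riboseq(s2, 2000L)
  expect_identical(r1, r2)
})

test_that("theta = 1 makes every internal codon optimal and CDSs validate", {
  cfg <- sim_config(n_genes = 8L, theta = 1, seed = 3L)
  sim <- simulate_genome(cfg)
  opt <- cfg$optimal_codons
  for (gid in sim$truth$gene_id) {
    g <- sim$genes[[gid]]
    expect_identical(g$cds_len %% 3L, 0L)
    cod <- codon_split(substr(g$tx_seq, 1, g$cds_len))
    internal <- cod[2:(length(cod) - 1L)]
    expect_true(all(internal %in% opt))
  }
  ## annotation written by the generator parses back
  p <- withr::local_tempfile()
  write_annotation(sim$genes, p)
  expect_identical(names(read_annotation(p)), names(sim$genes))
})

test_that("footprints place the P-site codon at read nts 13-15", {
  cfg <- sim_config(n_genes = 6L, seed = 9L,
                    footprint_length_probs = c("29" = 1),
                    footprint_jitter_probs = c("0" = 1))
  sim <- simulate_genome(cfg)
  reads <- simulate_riboseq(sim, 3000L)
  hits <- project_reads(reads, sim$genes)
  cod <- hits[hits$gene_id %in% sim$truth$gene_id, ]
  expect_true(all((cod$tpos5 + 12L) %% 3L == 0L))
  ## read nts 13-15 are the in-frame codon 12 nt downstream of the 5' end
  seqs <- reads$sequence[match(cod$read_id, reads$read_id)]
  gene_codon <- substr(
    vapply(sim$genes[cod$gene_id], `[[`, character(1), "tx_seq"),
    cod$tpos5 + 13L, cod$tpos5 + 15L)
  expect_identical(substr(seqs, 13L, 15L), unname(gene_codon))
})

test_that("with unit dwell the footprint 5' ends are uniform over codon starts", {
  cfg <- sim_config(n_genes = 2L, dwell_nonoptimal = 1,
                    structural_read_fraction = 0, seed = 21L,
                    abundance_sdlog = 0,
                    footprint_jitter_probs = c("0" = 1))
  sim <- simulate_genome(cfg)
  reads <- simulate_riboseq(sim, 50000L)
  hits <- project_reads(reads, sim$genes)
  gid <- sim$truth$gene_id[1L]
  t5 <- hits$tpos5[hits$gene_id == gid]
  k <- (t5 + 12L) / 3L
  eligible <- sim$meta[[gid]]$eligible_k
  obs <- table(factor(k, eligible))
  gof <- chisq.test(as.vector(obs))
  expect_gt(gof$p.value, 0.01)
})

test_that("planted TE decreases with non-optimal codon load", {
  sim <- simulate_genome(sim_config(n_genes = 50L, seed = 2L))
  expect_gt(cor(sim$truth$theta, sim$truth$te_true, method = "spearman"),
            0.95)
})

test_that("fully phased cleavage with 29-nt footprints lands every 22G at +29", {
  cfg <- sim_config(n_genes = 6L, p_phased = 1, p_polyU = 0,
                    footprint_length_probs = c("29" = 1),
                    footprint_jitter_probs = c("0" = 1),
                    structural_read_fraction = 0, seed = 13L)
  sim <- simulate_genome(cfg)
  ribo <- simulate_riboseq(sim, 5000L)
  srna <- simulate_smallrna(sim, ribo, "input", n_reads = 2000L)
  rhits <- project_reads(ribo, sim$genes)
  shits <- project_reads(srna$reads, sim$genes)
  expect_true(all(shits$orientation == "antisense"))
  by_gene_rpf <- split(rhits$tpos5, rhits$gene_id)
  ## genes with at least one footprint followed by a template C can host
  ## phased 22Gs; genes without fall back to background (documented)
  eligible <- vapply(names(by_gene_rpf), function(gid) {
    ch <- strsplit(sim$genes[[gid]]$tx_seq, "")[[1]]
    cand <- by_gene_rpf[[gid]] + 29L
    any(cand < length(ch) & ch[cand + 1L] == "C")
  }, logical(1))
  expect_gte(sum(eligible), 4L)
  use <- shits$gene_id %in% names(eligible)[eligible]
  ok <- mapply(function(gid, t5) t5 %in% (by_gene_rpf[[gid]] + 29L),
               shits$gene_id[use], shits$tpos5[use])
  expect_true(all(ok))
  ## every 22G starts with G (antisense-G site constraint)
  expect_true(all(startsWith(srna$reads$sequence, "G")))
})

test_that("p_polyU = 0 leaves FASTQ and TSV sequences identical", {
  cfg <- sim_config(n_genes = 5L, p_polyU = 0, seed = 8L)
  sim <- simulate_genome(cfg)
  ribo <- simulate_riboseq(sim, 2000L)
  srna <- simulate_smallrna(sim, ribo, "input", n_reads = 1000L)
  expect_identical(srna$fastq$sequence, srna$reads$sequence)
  expect_true(all(srna$tail_len == 0L))
})

test_that("planted IP enrichment is realized within the expected band", {
  ## equal abundances, 2% targets: realized ratio = 8 / (1 + 0.02 * 7)
  cfg <- sim_config(n_genes = 100L, abundance_sdlog = 0,
                    target_fraction = 0.02, ip_enrichment = 8,
                    structural_read_fraction = 0, p_polyU = 0,
                    n_srna_reads = 300000L, seed = 31L)
  sim <- simulate_genome(cfg)
  ribo <- simulate_riboseq(sim, 30000L)
  input <- simulate_smallrna(sim, ribo, "input")
  ip <- simulate_smallrna(sim, ribo, "ip", replicate = 1L)
  rpm_of <- function(reads) {
    hits <- project_reads(reads, sim$genes)
    counts <- rpm_normalize(count_reads(hits, sim$genes), sim$genes)
    setNames(counts$rpm, counts$gene_id)
  }
  ri <- rpm_of(input$reads); rp <- rpm_of(ip$reads)
  targets <- sim$truth$gene_id[sim$truth$is_target]
  ratio <- rp[targets] / ri[targets]
  expect_true(all(ratio >= 6 & ratio <= 10))
})

test_that("RNA-seq recovers abundance and covers transcripts evenly", {
  cfg <- sim_config(n_genes = 80L, seed = 17L, n_rnaseq_reads = 200000L)
  sim <- simulate_genome(cfg)
  rna <- simulate_rnaseq(sim)
  hits <- project_reads(rna, sim$genes)
  counts <- count_reads(hits, sim$genes)
  counts <- counts[counts$gene_id %in% sim$truth$gene_id, ]
  tpm <- compute_tpm(counts, effective_lengths(sim$genes, "transcript")
                     [sim$truth$gene_id])
  expect_gt(cor(tpm$tpm, sim$truth$abundance[match(tpm$gene_id,
                                                   sim$truth$gene_id)],
                method = "spearman"), 0.95)
  ## per-position coverage CV on the most abundant gene, away from the
  ## read-length ramp at the ends
  top <- sim$truth$gene_id[which.max(sim$truth$abundance)]
  cov <- coverage_by_gene(hits[hits$gene_id == top, ], sim$genes)[[top]]
  rl <- cfg$rnaseq_read_length
  core <- cov[(rl + 1L):(length(cov) - rl)]
  expect_lt(sd(core) / mean(core), 0.2)
})
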