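# Gene models, GFF3 I/O, transcript projection, RPM/TPM normalization.

test_that("GFF3 coordinates convert to 0-based half-open internally", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t250\t.\t+\t.\tID=g1;biotype=protein_coding",
    "chr1\tsrc\tCDS\t101\t190\t.\t+\t0\tParent=g1",
    "chr1\tsrc\tthree_prime_UTR\t191\t250\t.\t+\t.\tParent=g1"
  ), path)
  genes <- read_annotation(path)
  g <- genes[["g1"]]
  expect_identical(unname(g$cds[1, ]), c(100L, 190L))
  expect_identical(g$utr3, c(190L, 250L))
  expect_identical(g$cds_len, 90L)
})

test_that("a CDS whose length is not a multiple of 3 is rejected by name", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=bad",
    "chr1\tsrc\tCDS\t1\t100\t.\t+\t0\tParent=bad"
  ), path)
  expect_error(read_annotation(path), "bad.*not divisible by 3")
  expect_error(
    gene_model("g", "chr1", "+", matrix(c(0L, 100L), ncol = 2)),
    "not divisible by 3")
})

test_that("malformed GFF3 lines are reported with their line number", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t99",
               "chr1\tsrc\tgene\t1\t99\t.\t+\t.\tID=g"), path)
  expect_error(read_annotation(path), "line 2")
})

test_that("a multi-gene GFF3 round-trips bit-exactly and matches rtracklayer", {
  genes <- gene_set(list(toy_plus_gene(), toy_minus_gene(),
                         gene_model("sR", "chr1", "+",
                                    matrix(c(1100L, 1220L), ncol = 2),
                                    NULL, "rRNA")))
  p1 <- withr::local_tempfile(fileext = ".gff3")
  p2 <- withr::local_tempfile(fileext = ".gff3")
  write_annotation(genes, p1)
  back <- read_annotation(p1)
  expect_identical(names(back), names(genes))
  for (nm in names(genes)) {
    expect_identical(back[[nm]]$cds, genes[[nm]]$cds)
    expect_identical(back[[nm]]$utr3, genes[[nm]]$utr3)
    expect_identical(back[[nm]]$strand, genes[[nm]]$strand)
    expect_identical(back[[nm]]$biotype, genes[[nm]]$biotype)
  }
  write_annotation(back, p2)
  expect_identical(readLines(p1), readLines(p2))

  ## independent parser agrees on coordinates (1-based in, 0-based here)
  gr <- rtracklayer::import(p1)
  cds <- gr[gr$type == "CDS"]
  expect_setequal(GenomicRanges::start(cds) - 1L,
                  c(genes$gA$cds[, 1], genes$gB$cds[, 1]))
  expect_setequal(GenomicRanges::end(cds),
                  c(genes$gA$cds[, 2], genes$gB$cds[, 2]))
})

test_that("transcript projection follows the 5'-end conventions", {
  gA <- toy_plus_gene()
  ## sense read starting at 130 on a + gene with CDS [100,400)
  h <- project_to_transcript(toy_read("r1", 130, 160, "+"), gA)
  expect_identical(h$tpos5, 30L)
  expect_identical(h$region, "CDS")
  expect_identical(h$orientation, "sense")
  ## antisense read [150,172) on '-': its own 5' nt is genomic 171
  h <- project_to_transcript(toy_read("r2", 150, 172, "-"), gA)
  expect_identical(h$tpos5, 71L)
  expect_identical(h$orientation, "antisense")
  ## '-' strand gene: a sense read whose genomic 5' nt is the TSS
  gB <- toy_minus_gene()
  h <- project_to_transcript(toy_read("r3", 970, 1000, "-"), gB)
  expect_identical(h$tpos5, 0L)
  expect_identical(h$orientation, "sense")
  ## read 5' outside the transcript
  h <- project_to_transcript(toy_read("r4", 50, 80, "+"), gA)
  expect_identical(h$region, "outside")
  expect_true(is.na(h$tpos5))
})

test_that("projection is a bijection on spliced genes of both strands", {
  spliced_plus <- gene_model("sp", "chr1", "+",
                             matrix(c(100L, 280L, 400L, 220L, 340L, 451L),
                                    ncol = 2),
                             c(451L, 600L))
  spliced_minus <- gene_model("sm", "chr1", "-",
                              matrix(c(700L, 850L, 820L, 1000L), ncol = 2),
                              c(550L, 700L))
  for (g in list(spliced_plus, spliced_minus)) {
    tpos <- seq_len(g$tx_len) - 1L
    gpos <- tx_to_genomic(g, tpos)
    expect_false(anyNA(gpos))
    expect_identical(anyDuplicated(gpos), 0L)
    expect_identical(genomic_to_tx(g, gpos), tpos)
    ## monotone 5'->3' along the transcript
    expect_true(all(diff(gpos) != 0))
  }
})

test_that("RPM uses the non-structural denominator and ignores structural reads", {
  genes <- gene_set(list(
    toy_plus_gene(), toy_minus_gene(),
    gene_model("sR", "chr1", "+", matrix(c(1100L, 1220L), ncol = 2),
               NULL, "rRNA")))
  counts <- data.frame(gene_id = c("gA", "gB", "sR"),
                       library_id = "L1",
                       count = c(30L, 70L, 900L))
  rpm <- rpm_normalize(counts, genes)
  ## denominator is 100 (gA + gB), structural reads excluded
  expect_equal(rpm$rpm, c(30, 70, 900) * 1e6 / 100)
  ## adding a million rRNA reads changes nothing for the others
  counts2 <- counts
  counts2$count[3] <- counts2$count[3] + 1000000L
  rpm2 <- rpm_normalize(counts2, genes)
  expect_equal(rpm2$rpm[1:2], rpm$rpm[1:2])
  ## zero non-structural total errors
  counts3 <- counts
  counts3$count[1:2] <- 0L
  expect_error(rpm_normalize(counts3, genes), "zero non-structural")
})

test_that("TPM follows the length-normalized rate and sums to 1e6", {
  counts <- data.frame(gene_id = c("a", "b"), library_id = "L",
                       count = c(10L, 10L))
  tpm <- compute_tpm(counts, c(a = 100, b = 100))
  expect_equal(tpm$tpm, c(5e5, 5e5))
  ## doubling a gene's length halves its rate term
  tpm2 <- compute_tpm(counts, c(a = 200, b = 100))
  expect_equal(tpm2$tpm[1] / tpm2$tpm[2], 0.5)
  ## five-gene hand-computed oracle
  counts5 <- data.frame(gene_id = letters[1:5], library_id = "L",
                        count = c(12L, 0L, 33L, 5L, 50L))
  len5 <- c(a = 120, b = 300, c = 330, d = 50, e = 1000)
  rate <- counts5$count / len5
  expect_equal(compute_tpm(counts5, len5)$tpm, unname(rate / sum(rate) * 1e6))
  expect_equal(sum(compute_tpm(counts5, len5)$tpm), 1e6)
  expect_error(compute_tpm(data.frame(gene_id = "a", library_id = "L",
                                      count = 0L), c(a = 10)),
               "all counts zero")
})

test_that("transcript sequences reconstruct from genome + annotation", {
  sim <- simulate_genome(sim_config(n_genes = 6L, seed = 19L))
  stripped <- gene_set(lapply(sim$genes, function(g) {
    g$tx_seq <- NULL
    g
  }))
  back <- attach_tx_seq(stripped, as.list(sim$genome))
  for (nm in names(sim$genes))
    expect_identical(back[[nm]]$tx_seq, sim$genes[[nm]]$tx_seq)
})
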