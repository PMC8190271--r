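# Small-RNA classification, exact-match mapping, poly-U rescue,
# region counts, and composition profiles.

test_that("22G calls require leading G, window length, and antisense orientation", {
  gA <- toy_plus_gene()
  genes <- gene_set(list(gA))
  mk <- function(id, strand, seq) {
    start <- 150L
    toy_read(id, start, start + nchar(seq), strand, seq)
  }
  reads <- rbind(
    mk("anti_G", "-", paste0("G", strrep("A", 21))),   # 22 nt, G, antisense
    mk("anti_A", "-", paste0("A", strrep("G", 21))),   # leading A
    mk("sense_G", "+", paste0("G", strrep("A", 21))),  # sense
    mk("anti_G20", "-", paste0("G", strrep("A", 19))), # below window
    mk("anti_G24", "-", paste0("G", strrep("A", 23)))) # above window
  hits <- do.call(rbind, lapply(seq_len(nrow(reads)), function(i)
    project_to_transcript(reads[i, ], gA)))
  calls <- classify_small_rna(reads, hits, genes)
  expect_identical(calls$sclass,
                   c("G22", "other", "other", "other", "other"))
})

test_that("the exact-match toy mapper reports unique hits with 5'-end coordinates", {
  gA <- toy_plus_gene()
  gB <- toy_minus_gene()
  genes <- gene_set(list(gA, gB))
  index <- toy_index(genes)
  sense_frag <- substr(gA$tx_seq, 41, 62)              # tpos 40..61
  anti_frag <- revcomp(substr(gB$tx_seq, 101, 122))    # tpos 100..121
  hit <- toy_map(c(sense_frag, anti_frag, strrep("N", 22)), index)
  expect_identical(hit$mapped, c(TRUE, TRUE, FALSE))
  expect_identical(hit$gene_id[1:2], c("gA", "gB"))
  expect_identical(hit$orientation[1:2], c("sense", "antisense"))
  expect_identical(hit$tpos5[1:2], c(40L, 121L))  # antisense: downstream edge
  ## a read present in both genes is ambiguous and dropped
  genes_dup <- gene_set(list(gA, gB,
    gene_model("gC", "chr1", "+", matrix(c(2000L, 2300L), ncol = 2),
               NULL, "protein_coding",
               tx_seq = paste0(substr(gA$tx_seq, 1, 297), "TAA"))))
  hit2 <- toy_map(sense_frag, toy_index(genes_dup))
  expect_false(hit2$mapped)
  expect_gt(hit2$n_hits, 1L)
})

test_that("poly-U rescue trims maximal T-runs and enforces both length gates", {
  gA <- toy_plus_gene()
  genes <- gene_set(list(gA))
  index <- toy_index(genes)
  ## antisense 23-nt core starting with G somewhere in gA's CDS
  chars <- strsplit(gA$tx_seq, "")[[1]]
  idx <- which(chars == "C" & seq_along(chars) > 30 &
                 seq_along(chars) < gA$cds_len)
  idx <- idx[chars[idx - 22L] != "A"][1]  # core must not end in templated T
  csite <- idx - 1L                       # 0-based tpos
  core <- revcomp(substr(gA$tx_seq, csite - 21L, csite + 1L))  # 23 nt
  expect_identical(substr(core, 1, 1), "G")
  fq <- data.frame(
    read_id = c("tail3", "leadA", "short", "bare"),
    sequence = c(paste0(core, "TTT"),
                 paste0("A", strrep("C", 21), "TT"),
                 paste0("G", strrep("C", 19), "TT"),  # core 20 nt: too short
                 core),                               # no tail
    stringsAsFactors = FALSE)
  res <- rescue_polyU(fq, index)
  expect_identical(res$calls$sclass,
                   c("G22_polyU", "other", "other", "other"))
  expect_identical(res$calls$core_length[1], 23L)
  expect_identical(res$calls$tail_length[1], 3L)
  expect_identical(res$calls$gene_id[1], "gA")
  expect_identical(res$calls$tpos5[1], csite)
})

test_that("rescue decisions equal a regex plus brute-force substring oracle", {
  sim <- simulate_genome(sim_config(n_genes = 5L, n_structural_genes = 2L,
                                    seed = 71L))
  genes <- sim$genes
  index <- toy_index(genes)
  coding <- names(genes)[!phase22g:::is_structural(genes)]

  set.seed(72)
  mk_read <- function(kind) {
    gid <- sample(names(genes), 1L)
    tx <- genes[[gid]]$tx_seq
    switch(kind,
      anti_core = {       # true antisense core + tail, at a C site
        len <- sample(21:23, 1L)
        ch <- strsplit(tx, "")[[1]]
        i <- sample(which(ch == "C" & seq_along(ch) > len + 2L &
                            c(rep(FALSE, len - 1L),
                              head(ch, -(len - 1L)) != "A")), 1L)
        paste0(revcomp(substr(tx, i - len + 1L, i)),
               strrep("T", sample(1:4, 1L)))
      },
      random_cand = paste0("G", paste(sample(c("A", "C", "G"), sample(20:25, 1L),
                                             replace = TRUE), collapse = ""),
                           strrep("T", sample(1:3, 1L))),
      junk = paste(sample(c("A", "C", "G", "T"), sample(18:30, 1L),
                          replace = TRUE), collapse = ""),
      sense_core = {      # sense fragment + tail
        len <- sample(21:23, 1L)
        p <- sample(seq_len(nchar(tx) - len - 1L), 1L)
        paste0(substr(tx, p, p + len - 1L), strrep("T", sample(1:3, 1L)))
      })
  }
  seqs <- c(vapply(rep("anti_core", 400), mk_read, character(1)),
            vapply(rep("random_cand", 250), mk_read, character(1)),
            vapply(rep("junk", 200), mk_read, character(1)),
            vapply(rep("sense_core", 150), mk_read, character(1)))
  fq <- data.frame(read_id = sprintf("r%04d", seq_along(seqs)),
                   sequence = seqs, stringsAsFactors = FALSE)

  ## independent oracle: regex for candidacy; occurrence counting by
  ## exhaustive substring enumeration per transcript
  sub_table <- lapply(names(genes), function(gid) {
    tx <- genes[[gid]]$tx_seq
    do.call(rbind, lapply(20:26, function(l) {
      n <- nchar(tx)
      if (n < l) return(NULL)
      data.frame(sub = substring(tx, 1:(n - l + 1L), l:n), gene_id = gid,
                 pos = 0:(n - l), stringsAsFactors = FALSE)
    }))
  })
  sub_table <- do.call(rbind, sub_table)
  oracle <- vapply(seqs, function(s) {
    if (!grepl("^G[ACGTN]{20,25}T+$", s)) return("other")
    core <- sub("T+$", "", s)
    if (nchar(core) < 21L || nchar(core) > 26L) return("other")
    sense_hits <- sub_table[sub_table$sub == core, ]
    anti_hits <- sub_table[sub_table$sub == revcomp(core), ]
    if (nrow(sense_hits) + nrow(anti_hits) != 1L) return("other")
    if (nrow(anti_hits) == 1L && anti_hits$gene_id %in% coding &&
        nchar(core) >= 21L && nchar(core) <= 23L) "G22_polyU" else "other"
  }, character(1))

  res <- rescue_polyU(fq, index)
  expect_identical(res$calls$sclass, unname(oracle))
  ## ~5/7 of the 400 planted anti-cores come from coding genes
  expect_gt(sum(res$calls$sclass == "G22_polyU"), 200L)
})

test_that("simulated tailed reads are recovered by the rescue path", {
  run <- shared_run()
  stats <- run$srna$srna_input$rescue$stats
  expect_gte(stats[["rescued"]] / stats[["reads"]], 0.95)
})

test_that("region counts split 22G calls between CDS and 3'UTR", {
  genes <- gene_set(list(toy_plus_gene(), toy_minus_gene()))
  calls <- data.frame(
    read_id = sprintf("r%02d", 1:20),
    sclass = c(rep("G22", 12), rep("G22_polyU", 3), rep("other", 5)),
    gene_id = c(rep("gA", 10), rep("gB", 10)),
    region = c(rep("CDS", 7), rep("UTR3", 3),
               rep("CDS", 6), rep("UTR3", 4)),
    stringsAsFactors = FALSE)
  out <- count_by_region(calls, genes)
  get <- function(g, r) out$count[out$gene_id == g & out$region == r]
  ## hand count over the 15 G22/G22_polyU rows
  expect_identical(get("gA", "CDS"), 7L)
  expect_identical(get("gA", "UTR3"), 3L)
  expect_identical(get("gB", "CDS"), 5L)
  expect_identical(get("gB", "UTR3"), 0L)
  expect_equal(sum(out$rpm), 1e6)
})

test_that("composition profiles average per-gene proportions and scale by region composition", {
  ## gene whose CDS has exactly uniform base composition
  cds <- paste(rep("ACGT", 75), collapse = "")
  g <- gene_model("gU", "chr1", "+", matrix(c(0L, 300L), ncol = 2),
                  c(300L, 400L), "protein_coding",
                  paste0(cds, strrep("A", 100)))
  genes <- gene_set(list(g))
  calls <- data.frame(read_id = c("a", "b", "c"), gene_id = "gU",
                      region = "CDS", orientation = "sense",
                      stringsAsFactors = FALSE)
  seqs <- c(a = "GGA", b = "GCT", c = "GTT")
  prof <- composition_profile(calls, seqs, genes, "5prime",
                              positions = 3L)
  expect_equal(rowSums(prof), rep(1, 3))
  expect_equal(unname(prof[1, ]), c(0, 0, 1, 0))           # all start G
  expect_equal(unname(prof[2, ]), c(0, 1/3, 1/3, 1/3))
  expect_equal(unname(prof[3, ]), c(1/3, 0, 0, 2/3))
  ## uniform region composition (25% each) makes scaled = 4 x unscaled
  scaled <- composition_profile(calls, seqs, genes, "5prime",
                                scaled = TRUE, positions = 3L)
  expect_equal(scaled, prof * 4)
  ## 3'-anchored profile reads positions from the other end
  prof3 <- composition_profile(calls, seqs, genes, "3prime",
                               positions = 3L)
  expect_equal(unname(prof3[1, ]), c(1/3, 0, 0, 2/3))
})
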