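## Seeded synthetic genome and library generator.
##
## One synthetic chromosome carries protein-coding genes (ATG + internal
## codons drawn from planted optimal/non-optimal codon sets per a
## per-gene optimality fraction theta + stop + 3'UTR) interleaved with
## structural decoy genes. Ribo-seq footprints step codon-wise with
## elevated dwell at non-optimal A/P-site codons; antisense ~22-nt small
## RNAs start with 5'G and are either phased immediately 3' of a sampled
## (stalled) footprint or background-placed; a fraction carry
## non-templated 3' poly-U tails (FASTQ only); IP libraries up-weight
## planted target genes. Everything is deterministic under the config
## seed.

#' Simulation configuration
#'
#' All tunable study conditions in one validated list. Probabilities must
#' lie in `[0,1]` and distributions sum to 1. `theta` is the per-gene
#' fraction of internal codons drawn from the optimal set; `NULL` samples
#' it Uniform(0,1) per gene.
#'
#' @param n_genes number of protein-coding genes.
#' @param cds_codon_range min/max total codons per CDS (incl. start/stop).
#' @param utr3_range min/max 3'UTR length (nt).
#' @param optimal_codons,non_optimal_codons planted per-amino-acid codon
#'   sets (defaults from [planted_codon_sets()]).
#' @param theta per-gene optimal-codon fraction (`NULL`, scalar, or
#'   vector of length `n_genes`).
#' @param abundance_meanlog,abundance_sdlog log-normal mRNA abundance.
#' @param dwell_nonoptimal relative ribosome dwell weight when the A- or
#'   P-site codon is non-optimal (vs 1 otherwise).
#' @param footprint_length_probs distribution over footprint lengths
#'   28/29/30.
#' @param footprint_jitter_probs distribution over 5'-end digestion
#'   offsets -1/0/+1 nt relative to perfect codon registration
#'   (RNase trimming heterogeneity; the `0` class is the in-frame
#'   fraction used for A/P-site codon assignment).
#' @param p_phased probability a 22G 5' end is placed immediately 3' of a
#'   sampled footprint (else background).
#' @param phased_from_stalled if `TRUE`, phased 22Gs sample their source
#'   among footprints whose A- or P-site codon is non-optimal (cleavage
#'   downstream of stalled ribosomes).
#' @param background_utr3_fraction fraction of background 22G 5' ends
#'   placed in the 3'UTR.
#' @param p_polyU per-read probability of a non-templated 3' poly-U tail.
#' @param polyU_len_probs distribution over tail lengths 1..5.
#' @param srna_length_probs distribution over small-RNA core lengths
#'   21/22/23.
#' @param ip_enrichment IP/input sampling multiplier for planted targets.
#' @param target_fraction fraction of coding genes planted as IP targets.
#' @param n_structural_genes number of structural decoy genes.
#' @param structural_read_fraction fraction of each library drawn from
#'   structural genes.
#' @param n_riboseq_reads,n_rnaseq_reads,n_srna_reads library sizes.
#' @param n_ip_replicates IP replicate count.
#' @param rnaseq_read_length RNA-seq read length (nt).
#' @param spacer intergenic spacer length (nt).
#' @param structural_len structural gene length (nt).
#' @param seed integer RNG seed.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 200L,
                       cds_codon_range = c(150L, 450L),
                       utr3_range = c(100L, 300L),
                       optimal_codons = planted_codon_sets()$optimal,
                       non_optimal_codons = planted_codon_sets()$non_optimal,
                       theta = NULL,
                       abundance_meanlog = 4,
                       abundance_sdlog = 1,
                       dwell_nonoptimal = 4,
                       footprint_length_probs = c("28" = 0.25, "29" = 0.5,
                                                  "30" = 0.25),
                       footprint_jitter_probs = c("-2" = 0.1, "-1" = 0.2,
                                                  "0" = 0.5, "1" = 0.15,
                                                  "2" = 0.05),
                       p_phased = 0.8,
                       phased_from_stalled = TRUE,
                       background_utr3_fraction = 0.2,
                       p_polyU = 0.2,
                       polyU_len_probs = c("1" = 0.35, "2" = 0.25, "3" = 0.2,
                                           "4" = 0.12, "5" = 0.08),
                       srna_length_probs = c("21" = 0.2, "22" = 0.6,
                                             "23" = 0.2),
                       ip_enrichment = 8,
                       target_fraction = 0.05,
                       n_structural_genes = 10L,
                       structural_read_fraction = 0.1,
                       n_riboseq_reads = 150000L,
                       n_rnaseq_reads = 100000L,
                       n_srna_reads = 80000L,
                       n_ip_replicates = 2L,
                       rnaseq_read_length = 50L,
                       spacer = 200L,
                       structural_len = 120L,
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(cfg$p_phased, cfg$background_utr3_fraction, cfg$p_polyU,
             cfg$target_fraction, cfg$structural_read_fraction)
  if (any(probs < 0 | probs > 1))
    stop2("sim_config: probabilities must lie in [0, 1]")
  for (nm in c("footprint_length_probs", "footprint_jitter_probs",
               "polyU_len_probs", "srna_length_probs")) {
    p <- cfg[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop2("sim_config: ", nm, " must be a distribution summing to 1")
  }
  if (!is.null(theta) && any(theta < 0 | theta > 1))
    stop2("sim_config: theta must lie in [0, 1]")
  if (cfg$dwell_nonoptimal < 1)
    stop2("sim_config: dwell_nonoptimal must be >= 1")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

## eligible P-site codon indices and dwell weights for one gene.
## Overall codon index: 0 = ATG, 1..m internal, m+1 = stop. The P codon
## index k must give a footprint 5' end (3k - 12) inside the CDS and an
## A-site codon (k + 1) that is still an internal sense codon.
dwell_weights <- function(nonopt) {
  m <- length(nonopt)
  k <- seq(4L, m - 1L)
  list(k = k, stalled = nonopt[k] | nonopt[k + 1L])
}

#' Generate the synthetic genome, annotation, and truth table
#'
#' @param config a [sim_config()].
#' @return `sim_data` list: `genes` (a `gene_set` with transcript
#'   sequences), `genome` (named character, one chromosome), `truth`
#'   (per-gene data frame: theta, abundance, te_true, phased_fraction,
#'   is_target, ip_enrichment), `meta` (internal codon flags), `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  ng <- config$n_genes
  fam <- codon_families()
  multi_aa <- names(fam[lengths(fam) >= 2L])
  opt <- config$optimal_codons
  non <- config$non_optimal_codons

  theta <- config$theta %||% runif(ng)
  if (length(theta) == 1L) theta <- rep(theta, ng)
  abundance <- rlnorm(ng, config$abundance_meanlog, config$abundance_sdlog)
  n_target <- round(ng * config$target_fraction)
  is_target <- seq_len(ng) %in% sample.int(ng, n_target)

  gene_ids <- sprintf("g%03d", seq_len(ng))
  ncod <- sample(seq(config$cds_codon_range[1L], config$cds_codon_range[2L]),
                 ng, replace = TRUE)
  utr_len <- sample(seq(config$utr3_range[1L], config$utr3_range[2L]),
                    ng, replace = TRUE)
  strand <- sample(c("+", "-"), ng, replace = TRUE)

  tx_seq <- character(ng)
  meta <- vector("list", ng)
  te_raw <- numeric(ng)
  for (i in seq_len(ng)) {
    m <- ncod[i] - 2L
    aas <- sample(multi_aa, m, replace = TRUE)
    use_opt <- runif(m) < theta[i]
    codons <- ifelse(use_opt, opt[aas], non[aas])
    nonopt <- !use_opt
    cds <- paste0("ATG", paste(codons, collapse = ""),
                  sample(STOP_CODONS, 1L))
    utr <- random_dna(1L, utr_len[i])
    tx_seq[i] <- paste0(cds, utr)
    dw <- dwell_weights(nonopt)
    w <- ifelse(dw$stalled, config$dwell_nonoptimal, 1)
    te_raw[i] <- 1 / mean(w)
    meta[[i]] <- list(nonopt = nonopt, m = m,
                      eligible_k = dw$k, stalled = dw$stalled, weight = w)
  }
  te_true <- te_raw / mean(te_raw)

  ## structural decoys, interleaved at random slots
  ns <- config$n_structural_genes
  s_ids <- sprintf("s%03d", seq_len(ns))
  s_bio <- rep(c("rRNA", "tRNA", "snoRNA", "snRNA", "ncRNA"), length.out = ns)
  s_seq <- random_dna(ns, rep(config$structural_len, ns))
  s_strand <- sample(c("+", "-"), ns, replace = TRUE)

  order_all <- sample(c(seq_len(ng), -seq_len(ns)))
  chrom <- "chrS"
  segs <- character(0)
  pos <- 0L
  models <- list()
  spacer_seq <- function() random_dna(1L, config$spacer)
  for (idx in order_all) {
    segs <- c(segs, spacer_seq())
    pos <- pos + config$spacer
    if (idx > 0L) {
      i <- idx
      T <- nchar(tx_seq[i])
      cdsl <- 3L * ncod[i]
      gstart <- pos
      gend <- pos + T
      if (strand[i] == "+") {
        cds_iv <- c(gstart, gstart + cdsl)
        utr_iv <- c(gstart + cdsl, gend)
        gseq <- tx_seq[i]
      } else {
        cds_iv <- c(gstart + (T - cdsl), gend)
        utr_iv <- c(gstart, gstart + (T - cdsl))
        gseq <- revcomp(tx_seq[i])
      }
      models[[gene_ids[i]]] <- gene_model(gene_ids[i], chrom, strand[i],
                                          matrix(cds_iv, ncol = 2L), utr_iv,
                                          "protein_coding", tx_seq[i])
      segs <- c(segs, gseq)
      pos <- gend
    } else {
      j <- -idx
      L <- config$structural_len
      models[[s_ids[j]]] <- gene_model(
        s_ids[j], chrom, s_strand[j], matrix(c(pos, pos + L), ncol = 2L),
        NULL, s_bio[j],
        tx_seq = if (s_strand[j] == "+") s_seq[j] else revcomp(s_seq[j]))
      segs <- c(segs, s_seq[j])
      pos <- pos + L
    }
  }
  segs <- c(segs, spacer_seq())
  genome <- setNames(paste(segs, collapse = ""), chrom)

  truth <- data.frame(
    gene_id = gene_ids, theta = theta, abundance = abundance,
    te_true = te_true, phased_fraction = config$p_phased,
    is_target = is_target,
    ip_enrichment = ifelse(is_target, config$ip_enrichment, 1),
    cds_len = 3L * ncod, tx_len = nchar(tx_seq),
    stringsAsFactors = FALSE
  )
  structure(list(genes = gene_set(models), genome = genome, truth = truth,
                 meta = setNames(meta, gene_ids), config = config),
            class = "sim_data")
}

## genomic interval of a sense-strand transcript window [t5, t5+len) —
## vectorised over t5 for one (unspliced or spliced) gene.
tx_window_genomic <- function(gene, t5, len) {
  ga <- tx_to_genomic(gene, t5)
  gb <- tx_to_genomic(gene, t5 + len - 1L)
  data.frame(start = pmin(ga, gb), end = pmax(ga, gb) + 1L)
}

#' Simulate a Ribo-seq library
#'
#' Footprint counts per gene are proportional to
#' `abundance * te_true * internal codon count`; within a gene the
#' P-site codon index is sampled with weight `dwell_nonoptimal` when the
#' A- or P-site codon is non-optimal (else 1). The footprint 5' end is
#' placed 12 nt upstream of the P codon start so that read nts 13-15
#' cover the P-site codon and 16-18 the A-site codon; length is drawn
#' from `footprint_length_probs`. A `structural_read_fraction` of reads
#' is drawn uniformly from structural genes.
#'
#' @param sim a `sim_data` object.
#' @param n_reads library size (default from config).
#' @return read table (`library_id = "riboseq"`).
#' @export
simulate_riboseq <- function(sim, n_reads = NULL) {
  cfg <- sim$config
  set.seed(cfg$seed + 101L)
  n_reads <- n_reads %||% cfg$n_riboseq_reads
  n_struct <- round(n_reads * cfg$structural_read_fraction)
  n_code <- n_reads - n_struct
  tr <- sim$truth
  wgene <- tr$abundance * tr$te_true * (tr$cds_len / 3 - 2)
  counts <- as.vector(rmultinom(1L, n_code, wgene))
  lens <- as.integer(names(cfg$footprint_length_probs))

  rows <- vector("list", length(counts) + 1L)
  for (i in seq_along(counts)) {
    n <- counts[i]
    if (n == 0L) next
    gid <- tr$gene_id[i]
    gene <- sim$genes[[gid]]
    mt <- sim$meta[[gid]]
    ki <- sample(length(mt$eligible_k), n, replace = TRUE,
                 prob = ifelse(mt$stalled, cfg$dwell_nonoptimal, 1))
    k <- mt$eligible_k[ki]
    L <- sample_vals(lens, n, cfg$footprint_length_probs)
    jit <- sample_vals(as.integer(names(cfg$footprint_jitter_probs)), n,
                       cfg$footprint_jitter_probs)
    t5 <- pmax(3L * k - 12L + jit, 0L)
    iv <- tx_window_genomic(gene, t5, L)
    rows[[i]] <- data.frame(
      read_id = NA_character_, chrom = gene$chrom,
      start = iv$start, end = iv$end, strand = gene$strand,
      sequence = substr(rep(gene$tx_seq, n), t5 + 1L, t5 + L),
      library_id = "riboseq", stringsAsFactors = FALSE)
  }
  ## structural background
  if (n_struct > 0L) {
    sids <- names(sim$genes)[is_structural(sim$genes)]
    pick <- sample(sids, n_struct, replace = TRUE)
    L <- sample_vals(lens, n_struct, cfg$footprint_length_probs)
    slist <- lapply(split(seq_len(n_struct), pick), function(ri) {
      gene <- sim$genes[[pick[ri[1L]]]]
      Ls <- L[ri]
      t5 <- vapply(Ls, function(l) sample.int(gene$tx_len - l, 1L) - 1L,
                   integer(1))
      iv <- tx_window_genomic(gene, t5, Ls)
      data.frame(read_id = NA_character_, chrom = gene$chrom,
                 start = iv$start, end = iv$end, strand = gene$strand,
                 sequence = substr(rep(gene$tx_seq, length(ri)),
                                   t5 + 1L, t5 + Ls),
                 library_id = "riboseq", stringsAsFactors = FALSE)
    })
    rows[[length(counts) + 1L]] <- do.call(rbind, slist)
  }
  out <- do.call(rbind, rows)
  out$read_id <- sprintf("rpf%07d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

## cached per-gene C-template positions (eligible background 22G 5' sites)
c_sites <- function(gene, region, min_pos = 22L) {
  chars <- strsplit(gene$tx_seq, "")[[1L]]
  pos <- which(chars == "C") - 1L
  pos <- pos[pos >= min_pos]
  if (region == "CDS") pos[pos < gene$cds_len] else pos[pos >= gene$cds_len]
}

#' Simulate a small-RNA library (input or IP)
#'
#' Antisense reads of 21-23 nt whose 5' nucleotide is a G (template C).
#' With probability `p_phased` the 5' end is placed at
#' `footprint tpos5 + footprint length` of a footprint sampled from the
#' gene's Ribo-seq reads (restricted to stalled footprints when
#' `phased_from_stalled`), provided the site's template base is C;
#' otherwise (and for the `1 - p_phased` remainder) the 5' end is drawn
#' from background template-C sites in the CDS or 3'UTR. With probability
#' `p_polyU` a non-templated 3' T-run is appended in the FASTQ output
#' only; the read table always stores the templated core alignment. IP
#' libraries multiply each planted target's sampling weight by
#' `ip_enrichment`.
#'
#' @param sim a `sim_data` object.
#' @param ribo_reads read table from [simulate_riboseq()].
#' @param library `"input"` or `"ip"`.
#' @param replicate replicate number (seeds differ per replicate).
#' @param n_reads library size (default from config).
#' @return list: `reads` (read table of templated cores), `fastq`
#'   (data frame read_id, sequence including tails), `tail_len`
#'   (integer per read, 0 if untailed).
#' @export
simulate_smallrna <- function(sim, ribo_reads, library = c("input", "ip"),
                              replicate = 1L, n_reads = NULL) {
  library <- match.arg(library)
  cfg <- sim$config
  set.seed(cfg$seed + 211L + 17L * replicate + 1000L * (library == "ip"))
  n_reads <- n_reads %||% cfg$n_srna_reads
  lib_id <- if (library == "input") "srna_input"
            else sprintf("srna_ip_rep%d", replicate)
  tr <- sim$truth

  ## footprint 5' ends per gene, from the ribo library itself
  rhits <- project_reads(ribo_reads, sim$genes)
  rhits <- rhits[rhits$orientation == "sense" & rhits$region == "CDS", ]
  rhits <- rhits[rhits$gene_id %in% tr$gene_id, ]

  n_struct <- round(n_reads * cfg$structural_read_fraction)
  n_code <- n_reads - n_struct
  w <- tr$abundance
  if (library == "ip") w <- w * tr$ip_enrichment
  counts <- as.vector(rmultinom(1L, n_code, w))
  lens <- as.integer(names(cfg$srna_length_probs))
  tls <- as.integer(names(cfg$polyU_len_probs))

  by_gene <- split(rhits, rhits$gene_id)
  rows <- vector("list", length(counts))
  tails <- vector("list", length(counts))
  for (i in seq_along(counts)) {
    n <- counts[i]
    if (n == 0L) next
    gid <- tr$gene_id[i]
    gene <- sim$genes[[gid]]
    mt <- sim$meta[[gid]]
    chars <- strsplit(gene$tx_seq, "")[[1L]]

    ## phased candidate sites: cleavage immediately 3' of the ribosome.
    ## The cut is positioned by the ribosome's codon register (29 nt
    ## downstream of the in-frame footprint start, i.e. just past the
    ## true downstream edge), not by the observed footprint end, whose
    ## 5'/3' boundaries carry nuclease-trimming jitter
    fp <- by_gene[[gid]]
    ## in-frame-cut footprints carry an exact codon index and are an
    ## unbiased sample of ribosome positions
    if (!is.null(fp)) fp <- fp[(fp$tpos5 + 12L) %% 3L == 0L, , drop = FALSE]
    psites <- integer(0)
    if (!is.null(fp) && nrow(fp)) {
      k <- (fp$tpos5 + 12L) %/% 3L
      k <- pmax(pmin(k, mt$m - 1L), 1L)
      cand <- 3L * k + 17L
      ok <- cand < gene$tx_len & chars[cand + 1L] == "C"
      if (cfg$phased_from_stalled) {
        stalled <- mt$nonopt[k] | mt$nonopt[k + 1L]
        if (any(ok & stalled)) ok <- ok & stalled
      }
      psites <- cand[ok]
    }
    bg_cds <- c_sites(gene, "CDS")
    bg_utr <- c_sites(gene, "UTR3")

    ## background initiation is frame-balanced: the reading-frame residue
    ## (tpos mod 3) is drawn uniformly before picking a C site within it,
    ## so the null plants no 3-nt register (the planted codon sets give
    ## template Cs a strong frame bias that would otherwise leak a
    ## spurious period-3 signal into unphased libraries)
    bg_sample <- function(sites, n) {
      if (!length(sites)) return(integer(0))
      classes <- split(sites, sites %% 3L)
      ## exact allocation across residue classes (remainder randomized):
      ## sampling classes per read would leave binomial class-total
      ## fluctuations that are coherent across each residue row of the
      ## distance histogram and surface as spurious period-3 power
      nc <- length(classes)
      alloc <- rep(n %/% nc, nc)
      rem <- n %% nc
      if (rem > 0L) {
        extra <- sample.int(nc, rem)
        alloc[extra] <- alloc[extra] + 1L
      }
      out <- unlist(lapply(seq_len(nc), function(j)
        if (alloc[j] > 0L) sample_vals(classes[[j]], alloc[j])
        else integer(0)))
      out[sample.int(length(out))]
    }

    phased <- runif(n) < cfg$p_phased & length(psites) > 0L
    p <- integer(n)
    if (any(phased))
      p[phased] <- psites[sample.int(length(psites), sum(phased),
                                     replace = TRUE)]
    nb <- sum(!phased)
    if (nb > 0L) {
      in_utr <- runif(nb) < cfg$background_utr3_fraction &
        length(bg_utr) > 0L
      bg <- integer(nb)
      if (any(in_utr))
        bg[in_utr] <- bg_sample(bg_utr, sum(in_utr))
      if (any(!in_utr)) {
        if (!length(bg_cds))
          stop2("gene ", gid, ": no eligible G-start site in CDS")
        bg[!in_utr] <- bg_sample(bg_cds, sum(!in_utr))
      }
      p[!phased] <- bg
    }
    len <- sample_vals(lens, n, cfg$srna_length_probs)
    len <- pmin(len, p + 1L)  # read must fit the transcript 5' end

    ## non-templated tail: only at unambiguous sites — the tail's first
    ## T must be a true mismatch (template base 5'-ward of the read 3'
    ## end is not A, so the tailed read cannot map full-length) and the
    ## templated core must not itself end in T (a tail abutting a
    ## templated U-run has no identifiable boundary under maximal
    ## trimming)
    tail_mismatch <- ifelse(p - len >= 0L, chars[p - len + 1L], "A")
    core_end <- chars[p - len + 2L]
    tailed <- runif(n) < cfg$p_polyU & tail_mismatch != "A" & core_end != "A"
    tl <- integer(n)
    if (any(tailed))
      tl[tailed] <- sample_vals(tls, sum(tailed), cfg$polyU_len_probs)

    core <- revcomp(substr(rep(gene$tx_seq, n), p - len + 2L, p + 1L))
    iv <- tx_window_genomic(gene, p - len + 1L, len)
    rows[[i]] <- data.frame(
      read_id = NA_character_, chrom = gene$chrom,
      start = iv$start, end = iv$end,
      strand = if (gene$strand == "+") "-" else "+",
      sequence = core, library_id = lib_id, stringsAsFactors = FALSE)
    tails[[i]] <- tl
  }
  reads <- do.call(rbind, rows)
  tail_len <- unlist(tails) %||% integer(0)

  if (n_struct > 0L) {
    sids <- names(sim$genes)[is_structural(sim$genes)]
    pick <- sample(sids, n_struct, replace = TRUE)
    len <- sample_vals(lens, n_struct, cfg$srna_length_probs)
    slist <- lapply(split(seq_len(n_struct), pick), function(ri) {
      gene <- sim$genes[[pick[ri[1L]]]]
      ls <- len[ri]
      t5 <- vapply(ls, function(l) sample.int(gene$tx_len - l, 1L) - 1L,
                   integer(1))
      iv <- tx_window_genomic(gene, t5, ls)
      data.frame(read_id = NA_character_, chrom = gene$chrom,
                 start = iv$start, end = iv$end, strand = gene$strand,
                 sequence = substr(rep(gene$tx_seq, length(ri)),
                                   t5 + 1L, t5 + ls),
                 library_id = lib_id, stringsAsFactors = FALSE)
    })
    reads <- rbind(reads, do.call(rbind, slist))
    tail_len <- c(tail_len, integer(n_struct))
  }
  reads$read_id <- sprintf("%s_%07d", lib_id, seq_len(nrow(reads)))
  rownames(reads) <- NULL
  fastq <- data.frame(
    read_id = reads$read_id,
    sequence = paste0(reads$sequence, strrep("T", tail_len)),
    stringsAsFactors = FALSE)
  list(reads = reads, fastq = fastq, tail_len = tail_len)
}

#' Simulate an RNA-seq library
#'
#' Fragment 5' ends uniform over the transcript; per-gene counts
#' proportional to `abundance * transcript length`; sense strand.
#'
#' @inheritParams simulate_riboseq
#' @return read table (`library_id = "rnaseq"`).
#' @export
simulate_rnaseq <- function(sim, n_reads = NULL) {
  cfg <- sim$config
  set.seed(cfg$seed + 307L)
  n_reads <- n_reads %||% cfg$n_rnaseq_reads
  rl <- cfg$rnaseq_read_length
  tr <- sim$truth
  counts <- as.vector(rmultinom(1L, n_reads, tr$abundance * tr$tx_len))
  rows <- vector("list", length(counts))
  for (i in seq_along(counts)) {
    n <- counts[i]
    if (n == 0L) next
    gene <- sim$genes[[tr$gene_id[i]]]
    t5 <- sample.int(gene$tx_len - rl + 1L, n, replace = TRUE) - 1L
    iv <- tx_window_genomic(gene, t5, rl)
    rows[[i]] <- data.frame(
      read_id = NA_character_, chrom = gene$chrom,
      start = iv$start, end = iv$end, strand = gene$strand,
      sequence = substr(rep(gene$tx_seq, n), t5 + 1L, t5 + rl),
      library_id = "rnaseq", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$read_id <- sprintf("rna%07d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Write simulated data to an output directory
#'
#' Emits `genome.fa`, `genes.gff3`, `truth.tsv`, the four read TSVs and
#' `srna_raw.fastq` (input library, including poly-U tails).
#'
#' @param sim a `sim_data`.
#' @param libs list as returned by [simulate_all()].
#' @param outdir directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_sim <- function(sim, libs, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$genome), file.path(outdir, "genome.fa"))
  write_annotation(sim$genes, file.path(outdir, "genes.gff3"))
  write.table(sim$truth, file.path(outdir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_reads_tsv(libs$rnaseq, file.path(outdir, "reads_rnaseq.tsv"))
  write_reads_tsv(libs$riboseq, file.path(outdir, "reads_riboseq.tsv"))
  write_reads_tsv(libs$srna_input$reads,
                  file.path(outdir, "reads_srna_input.tsv"))
  ip_all <- do.call(rbind, lapply(libs$srna_ip, `[[`, "reads"))
  write_reads_tsv(ip_all, file.path(outdir, "reads_srna_ip.tsv"))
  write_fastq(libs$srna_input$fastq$read_id, libs$srna_input$fastq$sequence,
              file.path(outdir, "srna_raw.fastq"))
  invisible(outdir)
}

#' Simulate every library for one configuration
#'
#' @param config a [sim_config()].
#' @return list: `sim` (genome/truth), `riboseq`, `rnaseq`,
#'   `srna_input`, `srna_ip` (list of replicates).
#' @export
simulate_all <- function(config = sim_config()) {
  sim <- simulate_genome(config)
  ribo <- simulate_riboseq(sim)
  list(sim = sim,
       riboseq = ribo,
       rnaseq = simulate_rnaseq(sim),
       srna_input = simulate_smallrna(sim, ribo, "input"),
       srna_ip = lapply(seq_len(config$n_ip_replicates), function(r)
         simulate_smallrna(sim, ribo, "ip", replicate = r)))
}

#' Write a FASTQ file
#' @param ids read identifiers.
#' @param seqs read sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, seqs, path) {
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n",
                    strrep("I", nchar(seqs))), path)
  invisible(path)
}

#' Read a FASTQ file
#' @param path FASTQ path.
#' @return data frame: read_id, sequence.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub(" .*", "", names(x)),
             sequence = as.character(x), stringsAsFactors = FALSE)
}
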