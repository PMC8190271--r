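## Small-RNA classification, poly-U rescue, and composition profiles.

#' Classify aligned small-RNA reads
#'
#' A read is called `G22` when its sequence starts with G, its length
#' lies in the 22G window (default 21-23 nt inclusive), and it maps
#' antisense to a protein-coding gene; everything else is `other`.
#' Reads arriving through the poly-U rescue path are upgraded to
#' `G22_polyU` by [rescue_polyU()].
#'
#' @param reads read table.
#' @param hits matching hit table (same row order; see [project_reads()]
#'   applied to the same reads).
#' @param genes a `gene_set`.
#' @param len_window integer `c(min, max)` core length window.
#' @return calls data frame: read_id, sclass, core_length, tail_length,
#'   gene_id, orientation, region, tpos5.
#' @export
classify_small_rna <- function(reads, hits, genes,
                               len_window = c(21L, 23L)) {
  stopifnot(nrow(reads) == nrow(hits),
            all(reads$read_id == hits$read_id))
  len <- nchar(reads$sequence)
  biotype <- vapply(genes, `[[`, character(1), "biotype")[hits$gene_id]
  is_g22 <- startsWith(reads$sequence, "G") &
    len >= len_window[1L] & len <= len_window[2L] &
    hits$orientation == "antisense" &
    !is.na(biotype) & biotype == "protein_coding" &
    hits$region != "outside"
  data.frame(
    read_id = reads$read_id,
    sclass = ifelse(is_g22, "G22", "other"),
    core_length = len,
    tail_length = 0L,
    gene_id = hits$gene_id,
    orientation = hits$orientation,
    region = hits$region,
    tpos5 = hits$tpos5,
    library_id = reads$library_id,
    stringsAsFactors = FALSE
  )
}

#' Build an exact-match transcriptome index
#'
#' Deterministic toy mapper: a read maps where its full-length sequence
#' (sense) or reverse complement (antisense) occurs as an exact substring
#' of a transcript. A unique hit across both strands of all transcripts
#' is required; reads with zero or multiple hits are unmapped.
#'
#' @param genes a `gene_set` whose elements carry `tx_seq`.
#' @return index object for [toy_map()].
#' @export
toy_index <- function(genes) {
  has_seq <- !vapply(genes, function(g) is.null(g$tx_seq), logical(1))
  genes <- genes[has_seq]
  seqs <- vapply(genes, `[[`, character(1), "tx_seq")
  lens <- nchar(seqs)
  ## concatenate with a separator no read can span
  cat_seq <- paste(seqs, collapse = "#")
  offsets <- cumsum(c(0L, head(lens + 1L, -1L)))
  structure(list(cat = cat_seq, gene_id = names(genes), len = lens,
                 offset = offsets,
                 biotype = vapply(genes, `[[`, character(1), "biotype"),
                 cds_len = vapply(genes, `[[`, integer(1), "cds_len")),
            class = "toy_index")
}

## all exact occurrences of one pattern; returns 0-based starts
all_matches <- function(pattern, subject) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

#' Map reads exactly against a transcriptome index
#'
#' @param seqs character vector of read sequences.
#' @param index a [toy_index()].
#' @return data frame, one row per read: mapped (logical), gene_id,
#'   tpos5 (transcript coordinate of the read's own 5' nucleotide),
#'   orientation, region. Multi-hit reads are reported unmapped
#'   (`n_hits > 1`).
#' @export
toy_map <- function(seqs, index) {
  n <- length(seqs)
  out <- data.frame(mapped = logical(n), gene_id = NA_character_,
                    tpos5 = NA_integer_, orientation = NA_character_,
                    region = NA_character_, n_hits = 0L,
                    stringsAsFactors = FALSE)
  if (!n) return(out)
  rc <- revcomp(seqs)
  for (r in seq_len(n)) {
    len <- nchar(seqs[r])
    sh <- all_matches(seqs[r], index$cat)
    ah <- all_matches(rc[r], index$cat)
    nh <- length(sh) + length(ah)
    out$n_hits[r] <- nh
    if (nh != 1L) next
    pos <- if (length(sh)) sh else ah
    gi <- findInterval(pos, index$offset)
    ## reject matches spanning the separator
    if (pos + len > index$offset[gi] + index$len[gi]) next
    tstart <- pos - index$offset[gi]
    out$mapped[r] <- TRUE
    out$gene_id[r] <- index$gene_id[gi]
    if (length(sh)) {
      out$orientation[r] <- "sense"
      out$tpos5[r] <- tstart
    } else {
      out$orientation[r] <- "antisense"
      out$tpos5[r] <- tstart + len - 1L   # mRNA-downstream edge
    }
    out$region[r] <- if (out$tpos5[r] < index$cds_len[gi]) "CDS" else "UTR3"
  }
  out
}

#' Rescue poly-U-tailed small RNAs
#'
#' Among reads that failed initial full-length mapping, candidates are
#' those matching: a leading `G`, then 20 to 25 further nucleotides,
#' then a maximal run of one or more `T`s extending to the 3' end. The
#' whole trailing T-run is trimmed and the core re-mapped with the exact
#' toy mapper; a core that maps uniquely antisense to a protein-coding
#' gene and satisfies the 22G rules (leading G, core length within
#' `len_window`) is labelled `G22_polyU`, otherwise `other`.
#'
#' @param fastq data frame (read_id, sequence) of initially unmapped
#'   reads.
#' @param index a [toy_index()].
#' @param len_window 22G core-length window (as in
#'   [classify_small_rna()]).
#' @return list: `calls` (read_id, sclass, core_length, tail_length,
#'   gene_id, orientation, region, tpos5) and `stats` (candidates,
#'   remapped, rescued, dropped).
#' @export
rescue_polyU <- function(fastq, index, len_window = c(21L, 23L)) {
  seqs <- fastq$sequence
  core <- sub("T+$", "", seqs)
  tail_len <- nchar(seqs) - nchar(core)
  ## G + 20..25 nt core bound (21-26 nt including the leading G)
  candidate <- tail_len >= 1L & startsWith(core, "G") &
    nchar(core) >= 21L & nchar(core) <= 26L
  calls <- data.frame(read_id = fastq$read_id, sclass = "other",
                      core_length = nchar(core), tail_length = tail_len,
                      gene_id = NA_character_, orientation = NA_character_,
                      region = NA_character_, tpos5 = NA_integer_,
                      stringsAsFactors = FALSE)
  remapped <- 0L
  if (any(candidate)) {
    hit <- toy_map(core[candidate], index)
    remapped <- sum(hit$mapped)
    ok <- hit$mapped & !is.na(hit$orientation) &
      hit$orientation == "antisense" &
      index$biotype[match(hit$gene_id, index$gene_id)] == "protein_coding" &
      nchar(core[candidate]) >= len_window[1L] &
      nchar(core[candidate]) <= len_window[2L]
    ok[is.na(ok)] <- FALSE
    idx <- which(candidate)
    calls$sclass[idx[ok]] <- "G22_polyU"
    calls$gene_id[idx[hit$mapped]] <- hit$gene_id[hit$mapped]
    calls$orientation[idx[hit$mapped]] <- hit$orientation[hit$mapped]
    calls$region[idx[hit$mapped]] <- hit$region[hit$mapped]
    calls$tpos5[idx[hit$mapped]] <- hit$tpos5[hit$mapped]
  }
  list(calls = calls,
       stats = c(reads = nrow(fastq), candidates = sum(candidate),
                 remapped = remapped,
                 rescued = sum(calls$sclass == "G22_polyU"),
                 dropped = sum(candidate) - remapped))
}

#' Per-gene 22G counts split by region
#'
#' @param calls calls data frame ([classify_small_rna()] and/or rescue
#'   calls); only `G22`/`G22_polyU` rows are counted.
#' @param genes a `gene_set`.
#' @return data frame gene_id, region (CDS/UTR3), count, and rpm
#'   computed over non-structural 22G mappers.
#' @export
count_by_region <- function(calls, genes) {
  g22 <- calls[calls$sclass %in% c("G22", "G22_polyU") &
                 calls$region %in% c("CDS", "UTR3"), , drop = FALSE]
  grid <- expand.grid(gene_id = names(genes)[!is_structural(genes)],
                      region = c("CDS", "UTR3"), stringsAsFactors = FALSE)
  tab <- table(factor(g22$gene_id, unique(grid$gene_id)),
               factor(g22$region, c("CDS", "UTR3")))
  grid$count <- as.integer(tab[cbind(grid$gene_id, grid$region)])
  total <- sum(grid$count)
  grid$rpm <- if (total > 0) grid$count * 1e6 / total else 0
  grid
}

## per-gene base composition of a region sequence, on the strand the
## reads map to
region_composition <- function(gene, region, read_strand_sense,
                               utr3_limit = 100L) {
  if (region == "CDS") {
    seq <- substr(gene$tx_seq, 1L, gene$cds_len)
  } else {
    utr <- substr(gene$tx_seq, gene$cds_len + 1L, gene$tx_len)
    seq <- substr(utr, 1L, min(nchar(utr), utr3_limit))
  }
  if (!read_strand_sense) seq <- revcomp(seq)
  chars <- strsplit(seq, "")[[1L]]
  tab <- table(factor(chars, DNA))
  as.numeric(tab) / length(chars)
}

#' Per-position nucleotide composition of a read set
#'
#' Computes, for reads grouped by gene, the proportion of each
#' nucleotide at each position counted from the 5' or the 3' end, then
#' averages the per-gene matrices across the gene set with equal weight.
#' The scaled variant first divides each gene's proportions by the base
#' composition of the genomic region its reads map to (CDS, or the
#' first 100 bp of the 3'UTR), taken on the reads' strand.
#'
#' @param calls calls data frame carrying gene_id, region and read
#'   sequences (joined via `sequences`).
#' @param sequences named character vector: read_id -> sequence.
#' @param genes a `gene_set`.
#' @param anchor `"5prime"` or `"3prime"`.
#' @param region `"CDS"` or `"UTR3"` (reads filtered to it).
#' @param scaled divide by region base composition before averaging.
#' @param positions number of positions to report.
#' @return matrix `positions x 4` (A, C, G, T); unscaled rows sum to 1.
#' @export
composition_profile <- function(calls, sequences, genes,
                                anchor = c("5prime", "3prime"),
                                region = "CDS", scaled = FALSE,
                                positions = 25L) {
  anchor <- match.arg(anchor)
  use <- calls[calls$region == region & !is.na(calls$gene_id), , drop = FALSE]
  if (!nrow(use)) stop2("composition_profile: no reads in region ", region)
  per_gene <- lapply(split(use, use$gene_id), function(part) {
    seqs <- sequences[part$read_id]
    if (anchor == "3prime")
      seqs <- vapply(strsplit(seqs, ""), function(x)
        paste(rev(x), collapse = ""), character(1))
    mat <- matrix(0, positions, 4L, dimnames = list(NULL, DNA))
    for (p in seq_len(positions)) {
      b <- substr(seqs, p, p)
      b <- b[nzchar(b)]
      if (!length(b)) next
      tab <- table(factor(b, DNA))
      mat[p, ] <- as.numeric(tab) / length(b)
    }
    if (scaled) {
      gene <- genes[[part$gene_id[1L]]]
      sense <- part$orientation[1L] == "sense"
      comp <- region_composition(gene, region, sense)
      mat <- sweep(mat, 2L, ifelse(comp > 0, comp, NA), "/")
    }
    mat
  })
  Reduce(`+`, per_gene) / length(per_gene)
}
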