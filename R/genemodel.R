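## Gene models and transcript-coordinate machinery.
##
## Internal convention: all genomic intervals are 0-based half-open.
## GFF3 input/output converts to/from 1-based inclusive at the boundary.
## A transcript is the spliced CDS followed by the 3'UTR (no 5'UTR in this
## model); transcript coordinates run 5'->3' of the mRNA and are 0-based.

STRUCTURAL_BIOTYPES <- c("tRNA", "rRNA", "snRNA", "snoRNA", "ncRNA")
BIOTYPES <- c("protein_coding", STRUCTURAL_BIOTYPES)

#' Construct a gene model
#'
#' @param gene_id identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cds two-column matrix of 0-based half-open genomic intervals
#'   (`start`, `end`), ordered 5' to 3' along the transcript (ascending
#'   starts on `+`, descending on `-`). For structural genes this is the
#'   single gene span.
#' @param utr3 length-2 vector `c(start, end)` (0-based half-open) or
#'   `NULL`; must abut the 3' end of the CDS on the gene's strand.
#' @param biotype one of `protein_coding`, `tRNA`, `rRNA`, `snRNA`,
#'   `snoRNA`, `ncRNA`.
#' @param tx_seq optional transcript sequence (mRNA sense, CDS then 3'UTR).
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, cds, utr3 = NULL,
                       biotype = "protein_coding", tx_seq = NULL) {
  stopifnot(strand %in% c("+", "-"), biotype %in% BIOTYPES)
  cds <- matrix(as.integer(cds), ncol = 2L,
                dimnames = list(NULL, c("start", "end")))
  if (any(cds[, 2L] <= cds[, 1L]))
    stop2("gene ", gene_id, ": empty or inverted CDS interval")
  o <- order(cds[, 1L])
  if (nrow(cds) > 1L && any(cds[o, 2L][-nrow(cds)] > cds[o, 1L][-1L]))
    stop2("gene ", gene_id, ": overlapping CDS intervals")
  ## store in transcript order
  cds <- if (strand == "+") cds[o, , drop = FALSE] else cds[rev(o), , drop = FALSE]
  cds_len <- sum(cds[, 2L] - cds[, 1L])
  if (biotype == "protein_coding" && cds_len %% 3L != 0L)
    stop2("gene ", gene_id, ": CDS length ", cds_len, " not divisible by 3")
  if (!is.null(utr3)) {
    utr3 <- as.integer(utr3)
    three_end <- if (strand == "+") max(cds[, 2L]) else min(cds[, 1L])
    ok <- if (strand == "+") utr3[1L] == three_end else utr3[2L] == three_end
    if (!ok)
      stop2("gene ", gene_id, ": 3'UTR does not abut the CDS 3' end")
  }
  g <- list(gene_id = gene_id, chrom = chrom, strand = strand,
            biotype = biotype, cds = cds, utr3 = utr3,
            cds_len = cds_len,
            tx_len = cds_len + if (is.null(utr3)) 0L else utr3[2L] - utr3[1L],
            tx_seq = tx_seq)
  class(g) <- "gene_model"
  g
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s) %s CDS %d nt, tx %d nt\n",
              x$gene_id, x$chrom, gene_span(x)[1L], gene_span(x)[2L],
              x$strand, x$biotype, x$cds_len, x$tx_len))
  invisible(x)
}

#' Genomic span of a gene model
#' @param gene a `gene_model`.
#' @return integer `c(start, end)`, 0-based half-open.
#' @export
gene_span <- function(gene) {
  lo <- min(gene$cds[, 1L], if (is.null(gene$utr3)) Inf else gene$utr3[1L])
  hi <- max(gene$cds[, 2L], if (is.null(gene$utr3)) -Inf else gene$utr3[2L])
  c(as.integer(lo), as.integer(hi))
}

## ordered transcript segments: one row per (genomic interval, direction),
## in transcript order, with cumulative transcript offsets.
tx_segments <- function(gene) {
  segs <- gene$cds
  if (!is.null(gene$utr3)) segs <- rbind(segs, gene$utr3)
  len <- segs[, 2L] - segs[, 1L]
  data.frame(gstart = segs[, 1L], gend = segs[, 2L], len = len,
             off = cumsum(c(0L, len))[seq_along(len)])
}

#' Map genomic positions to transcript coordinates
#'
#' @param gene a `gene_model`.
#' @param gpos integer vector of 0-based genomic positions.
#' @return integer vector of 0-based transcript positions; `NA` where the
#'   position falls outside the transcript.
#' @export
genomic_to_tx <- function(gene, gpos) {
  segs <- tx_segments(gene)
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_len(nrow(segs))) {
    inside <- !is.na(gpos) & gpos >= segs$gstart[i] & gpos < segs$gend[i]
    if (!any(inside)) next
    out[inside] <- if (gene$strand == "+")
      segs$off[i] + (gpos[inside] - segs$gstart[i])
    else
      segs$off[i] + (segs$gend[i] - 1L - gpos[inside])
  }
  out
}

#' Map transcript coordinates to genomic positions
#'
#' Inverse of [genomic_to_tx()].
#' @inheritParams genomic_to_tx
#' @param tpos integer vector of 0-based transcript positions.
#' @return integer vector of 0-based genomic positions (`NA` outside).
#' @export
tx_to_genomic <- function(gene, tpos) {
  segs <- tx_segments(gene)
  out <- rep(NA_integer_, length(tpos))
  for (i in seq_len(nrow(segs))) {
    inside <- !is.na(tpos) & tpos >= segs$off[i] & tpos < segs$off[i] + segs$len[i]
    if (!any(inside)) next
    d <- tpos[inside] - segs$off[i]
    out[inside] <- if (gene$strand == "+") segs$gstart[i] + d
                   else segs$gend[i] - 1L - d
  }
  out
}

#' Attach transcript sequences to a gene set from a genome
#'
#' Reconstructs each gene's mRNA-sense transcript sequence (spliced CDS
#' followed by 3'UTR) from chromosome sequences, reverse-complementing
#' minus-strand genes.
#'
#' @param genes a `gene_set`.
#' @param genome named character vector of chromosome sequences (e.g.
#'   from `Biostrings::readDNAStringSet` coerced with `as.character`).
#' @return the `gene_set` with `tx_seq` filled in.
#' @export
attach_tx_seq <- function(genes, genome) {
  out <- lapply(genes, function(g) {
    chrom <- genome[[g$chrom]]
    if (is.null(chrom)) stop2("attach_tx_seq: missing chromosome ", g$chrom)
    segs <- tx_segments(g)
    pieces <- substring(chrom, segs$gstart + 1L, segs$gend)
    if (g$strand == "-") pieces <- revcomp(pieces)
    g$tx_seq <- paste(pieces, collapse = "")
    g
  })
  gene_set(out)
}

#' Assemble a gene set
#'
#' @param genes list of `gene_model` objects (non-overlapping loci).
#' @return a named `gene_set` (list keyed by `gene_id`).
#' @export
gene_set <- function(genes) {
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
  structure(genes, class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  bt <- table(vapply(x, `[[`, character(1), "biotype"))
  cat("<gene_set> ", length(x), " genes (",
      paste(names(bt), bt, sep = ":", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
`[.gene_set` <- function(x, i) {
  structure(unclass(x)[i], class = "gene_set")
}

#' Summarize a gene set as a data frame
#' @param genes a `gene_set`.
#' @return data frame with one row per gene.
#' @export
genes_df <- function(genes) {
  span <- t(vapply(genes, gene_span, integer(2)))
  data.frame(
    gene_id = vapply(genes, `[[`, character(1), "gene_id"),
    chrom = vapply(genes, `[[`, character(1), "chrom"),
    start = span[, 1L], end = span[, 2L],
    strand = vapply(genes, `[[`, character(1), "strand"),
    biotype = vapply(genes, `[[`, character(1), "biotype"),
    cds_len = vapply(genes, `[[`, integer(1), "cds_len"),
    tx_len = vapply(genes, `[[`, integer(1), "tx_len"),
    row.names = NULL
  )
}

is_structural <- function(genes) {
  vapply(genes, `[[`, character(1), "biotype") %in% STRUCTURAL_BIOTYPES
}

## ---------------------------------------------------------------- GFF3 I/O

gff3_attr <- function(attr, key) {
  m <- regmatches(attr, regexec(paste0("(?:^|;)", key, "=([^;]*)"), attr))
  vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_,
         character(1))
}

#' Read gene models from a GFF3 file
#'
#' Expects `gene` features (with `ID` and optional `biotype` attributes,
#' default `protein_coding`) and, for coding genes, `CDS` and
#' `three_prime_UTR` features carrying a `Parent` attribute. GFF3
#' coordinates (1-based inclusive) are converted to the internal 0-based
#' half-open convention.
#'
#' @param path GFF3 file path.
#' @return a `gene_set`.
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad))
    stop2("malformed GFF3 line ", lineno[bad[1L]], " in ", path,
          ": expected 9 tab-separated fields, got ", lengths(fields)[bad[1L]])
  tab <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(tab) <- c("seqid", "source", "type", "start", "end",
                  "score", "strand", "phase", "attr")
  start <- suppressWarnings(as.integer(tab$start))
  end <- suppressWarnings(as.integer(tab$end))
  if (anyNA(start) || anyNA(end))
    stop2("malformed GFF3 line ", lineno[which(is.na(start) | is.na(end))[1L]],
          ": non-numeric coordinates")
  tab$start0 <- start - 1L   # to 0-based half-open
  tab$end0 <- end
  genes_rows <- tab[tab$type == "gene", , drop = FALSE]
  if (!nrow(genes_rows)) stop2("no gene features in ", path)
  out <- vector("list", nrow(genes_rows))
  for (i in seq_len(nrow(genes_rows))) {
    row <- genes_rows[i, ]
    gid <- gff3_attr(row$attr, "ID")
    if (is.na(gid)) stop2("gene feature without ID attribute in ", path)
    biotype <- gff3_attr(row$attr, "biotype")
    if (is.na(biotype)) biotype <- "protein_coding"
    if (!biotype %in% BIOTYPES)
      stop2("gene ", gid, ": unknown biotype '", biotype, "'")
    child <- tab$type %in% c("CDS", "three_prime_UTR") &
      gff3_attr(tab$attr, "Parent") == gid
    cds_rows <- tab[child & tab$type == "CDS", , drop = FALSE]
    utr_rows <- tab[child & tab$type == "three_prime_UTR", , drop = FALSE]
    if (biotype == "protein_coding" && !nrow(cds_rows))
      stop2("gene ", gid, ": protein_coding gene without CDS features")
    cds <- if (nrow(cds_rows)) cbind(cds_rows$start0, cds_rows$end0)
           else cbind(row$start0, row$end0)
    utr3 <- if (nrow(utr_rows)) {
      c(min(utr_rows$start0), max(utr_rows$end0))
    } else NULL
    out[[i]] <- gene_model(gid, row$seqid, row$strand, cds, utr3, biotype)
  }
  gene_set(out)
}

#' Write gene models to a GFF3 file
#'
#' Inverse of [read_annotation()]; coordinates are emitted 1-based
#' inclusive so that a read/write round trip is bit-exact.
#'
#' @param genes a `gene_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in genes) {
    span <- gene_span(g)
    writeLines(sprintf("%s\tphase22g\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
                       g$chrom, span[1L] + 1L, span[2L], g$strand,
                       g$gene_id, g$biotype), con)
    if (g$biotype == "protein_coding") {
      cds <- g$cds[order(g$cds[, 1L]), , drop = FALSE]
      for (j in seq_len(nrow(cds)))
        writeLines(sprintf("%s\tphase22g\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                           g$chrom, cds[j, 1L] + 1L, cds[j, 2L], g$strand,
                           g$gene_id), con)
      if (!is.null(g$utr3))
        writeLines(sprintf(
          "%s\tphase22g\tthree_prime_UTR\t%d\t%d\t.\t%s\t.\tParent=%s",
          g$chrom, g$utr3[1L] + 1L, g$utr3[2L], g$strand, g$gene_id), con)
    }
  }
  invisible(path)
}
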