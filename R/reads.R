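## Aligned-read records and their projection into transcript space.
##
## Reads travel as plain data frames ("read table") with columns
## chrom, start, end (0-based half-open), read_id, strand, sequence,
## library_id — i.e. BED6-compatible column content plus sequence and
## library. A "hit table" adds gene_id, tpos5, orientation, region.

READ_COLS <- c("read_id", "chrom", "start", "end", "strand",
               "sequence", "library_id")

validate_reads <- function(reads) {
  miss <- setdiff(READ_COLS, names(reads))
  if (length(miss)) stop2("read table missing columns: ",
                          paste(miss, collapse = ", "))
  bad <- which(reads$end - reads$start != nchar(reads$sequence))
  if (length(bad))
    stop2("read ", reads$read_id[bad[1L]],
          ": interval length differs from sequence length")
  if (any(grepl("[^ACGTN]", reads$sequence)))
    stop2("read sequences must be over the ACGTN alphabet")
  invisible(reads)
}

#' Read an aligned-read table (extended BED6 TSV)
#'
#' Columns: chrom, start, end, read_id, score, strand, sequence,
#' library_id; coordinates 0-based half-open as in BED.
#'
#' @param path TSV file path.
#' @return read-table data frame.
#' @export
read_reads_tsv <- function(path) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  tab$score <- NULL
  validate_reads(tab)
  tab
}

#' Write an aligned-read table
#' @param reads read-table data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reads_tsv <- function(reads, path) {
  validate_reads(reads)
  out <- data.frame(chrom = reads$chrom, start = reads$start, end = reads$end,
                    read_id = reads$read_id, score = ".",
                    strand = reads$strand, sequence = reads$sequence,
                    library_id = reads$library_id)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' 5'-end genomic position of each read
#' @param reads read table.
#' @return integer vector (0-based): `start` for `+` reads, `end - 1`
#'   for `-` reads.
#' @export
read_5prime <- function(reads) {
  ifelse(reads$strand == "+", reads$start, reads$end - 1L)
}

#' Assign reads to genes by their 5' position
#'
#' Genes must occupy non-overlapping loci on each chromosome. A read is
#' assigned to the gene whose span contains its 5' nucleotide.
#'
#' @param reads read table.
#' @param genes a `gene_set`.
#' @return character vector of gene ids (`NA` where unassigned).
#' @export
assign_gene <- function(reads, genes) {
  gdf <- genes_df(genes)
  p5 <- read_5prime(reads)
  out <- rep(NA_character_, nrow(reads))
  for (chr in unique(gdf$chrom)) {
    gi <- gdf[gdf$chrom == chr, ]
    gi <- gi[order(gi$start), ]
    ri <- which(reads$chrom == chr)
    if (!length(ri)) next
    idx <- findInterval(p5[ri], gi$start)
    hit <- idx >= 1L & p5[ri] < gi$end[pmax(idx, 1L)]
    out[ri[hit]] <- gi$gene_id[idx[hit]]
  }
  out
}

#' Project reads onto a gene's transcript coordinates
#'
#' The transcript position reported (`tpos5`) is that of the read's own
#' 5' nucleotide: for a sense read this is its genomic start (on `+`
#' genes), for an antisense read it is the mRNA-downstream edge of its
#' span. Orientation is `sense` iff read strand equals gene strand;
#' region is decided by the transcript segment containing `tpos5`
#' (`CDS`, `UTR3`, or `outside` when the 5' nucleotide falls outside the
#' transcript).
#'
#' @param reads read table (rows overlapping `gene`'s locus).
#' @param gene a `gene_model`.
#' @return hit table: read_id, gene_id, tpos5, orientation, region.
#' @export
project_to_transcript <- function(reads, gene) {
  p5 <- read_5prime(reads)
  tpos5 <- genomic_to_tx(gene, p5)
  region <- ifelse(is.na(tpos5), "outside",
                   ifelse(tpos5 < gene$cds_len, "CDS", "UTR3"))
  data.frame(
    read_id = reads$read_id,
    gene_id = gene$gene_id,
    tpos5 = tpos5,
    orientation = ifelse(reads$strand == gene$strand, "sense", "antisense"),
    region = region,
    length = nchar(reads$sequence),
    library_id = reads$library_id,
    stringsAsFactors = FALSE
  )
}

#' Project a read table onto all genes of a gene set
#'
#' Assigns each read to the gene containing its 5' nucleotide and
#' projects it into that gene's transcript frame; unassigned reads are
#' dropped.
#'
#' @param reads read table.
#' @param genes a `gene_set`.
#' @return hit table with one row per assigned read.
#' @export
project_reads <- function(reads, genes) {
  gid <- assign_gene(reads, genes)
  keep <- !is.na(gid)
  reads <- reads[keep, , drop = FALSE]
  gid <- gid[keep]
  parts <- lapply(split(seq_len(nrow(reads)), gid), function(ri) {
    project_to_transcript(reads[ri, , drop = FALSE], genes[[gid[ri[1L]]]])
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
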