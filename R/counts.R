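## Counts tables and library-size normalization.
##
## A counts table is a data frame with one row per (gene_id, library_id):
## columns gene_id, library_id, count, and after normalization rpm
## and/or tpm. RPM divides by the library's non-structural mapper total
## (structural genes — tRNA, rRNA, snRNA, snoRNA, ncRNA — are excluded
## from the denominator but still receive values); TPM is the standard
## length-normalized rate scaled to 1e6 per library.

#' Count assigned reads per gene and library
#'
#' @param hits hit table (see [project_reads()]); rows with
#'   `region == "outside"` are ignored.
#' @param genes a `gene_set`; genes without reads get zero rows.
#' @param orientation optional filter: `"sense"` or `"antisense"`.
#' @return counts table (gene_id, library_id, count).
#' @export
count_reads <- function(hits, genes, orientation = NULL) {
  hits <- hits[hits$region != "outside", , drop = FALSE]
  if (!is.null(orientation))
    hits <- hits[hits$orientation == orientation, , drop = FALSE]
  libs <- sort(unique(hits$library_id))
  if (!length(libs)) libs <- "library"
  grid <- expand.grid(gene_id = names(genes), library_id = libs,
                      stringsAsFactors = FALSE)
  tab <- table(factor(hits$gene_id, names(genes)),
               factor(hits$library_id, libs))
  grid$count <- as.integer(tab[cbind(grid$gene_id, grid$library_id)])
  grid
}

#' RPM normalization over non-structural mappers
#'
#' `rpm = count * 1e6 / N_lib` where `N_lib` is the library's total count
#' over non-structural genes only. Adding structural-gene (tRNA, rRNA,
#' snRNA, snoRNA, ncRNA) reads therefore leaves every rpm unchanged.
#'
#' @param counts counts table.
#' @param genes a `gene_set` supplying biotypes.
#' @return `counts` with an `rpm` column.
#' @export
rpm_normalize <- function(counts, genes) {
  structural <- names(genes)[is_structural(genes)]
  ns <- !(counts$gene_id %in% structural)
  totals <- tapply(counts$count[ns], counts$library_id[ns], sum)
  if (any(is.na(totals)) || any(totals == 0))
    stop2("rpm_normalize: a library has zero non-structural mappers")
  counts$rpm <- counts$count * 1e6 / as.numeric(totals[counts$library_id])
  counts
}

#' Transcripts-per-million normalization
#'
#' `tpm_g = (count_g / len_g) / sum_g'(count_g' / len_g') * 1e6` within
#' each library.
#'
#' @param counts counts table.
#' @param effective_lengths named numeric vector, nt per gene. Use CDS
#'   length for ribosome footprints and transcript length for mRNA-seq.
#' @return `counts` with a `tpm` column.
#' @export
compute_tpm <- function(counts, effective_lengths) {
  len <- effective_lengths[counts$gene_id]
  if (anyNA(len)) stop2("compute_tpm: missing effective length for ",
                        counts$gene_id[which(is.na(len))[1L]])
  if (any(len <= 0)) stop2("compute_tpm: effective lengths must be positive")
  rate <- counts$count / len
  denom <- tapply(rate, counts$library_id, sum)
  if (any(denom == 0)) stop2("compute_tpm: all counts zero in a library")
  counts$tpm <- rate / as.numeric(denom[counts$library_id]) * 1e6
  counts
}

#' Effective lengths for a gene set
#' @param genes a `gene_set`.
#' @param mode `"cds"` or `"transcript"`.
#' @return named numeric vector.
#' @export
effective_lengths <- function(genes, mode = c("cds", "transcript")) {
  mode <- match.arg(mode)
  v <- vapply(genes, `[[`, integer(1), if (mode == "cds") "cds_len" else "tx_len")
  setNames(as.numeric(v), names(genes))
}
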