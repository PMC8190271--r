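## Ribosome-protected fragments: selection, A/P-site codons, TE.

#' Select ribosome-protected fragments
#'
#' Keeps reads of 28-30 nt mapping sense to a protein-coding gene with
#' their 5' end inside the CDS.
#'
#' @param hits hit table from [project_reads()].
#' @param genes a `gene_set`.
#' @param len_window integer `c(min, max)`, default 28-30 nt.
#' @return RPF table: read_id, gene_id, tpos5, length, library_id.
#' @export
select_rpf <- function(hits, genes, len_window = c(28L, 30L)) {
  biotype <- vapply(genes, `[[`, character(1), "biotype")[hits$gene_id]
  keep <- hits$orientation == "sense" &
    hits$region == "CDS" &
    hits$length >= len_window[1L] & hits$length <= len_window[2L] &
    biotype == "protein_coding"
  out <- hits[keep, c("read_id", "gene_id", "tpos5", "length", "library_id")]
  rownames(out) <- NULL
  out
}

#' Assign A- and P-site codons to 29-nt footprints
#'
#' Within a 29-nt footprint the P site occupies read nucleotides 13-15
#' and the A site 16-18 (1-based). Codons are read off the gene's CDS;
#' footprints whose P-site window does not start on an in-frame codon
#' boundary are flagged `in_frame = FALSE` and should be excluded from
#' codon-stratified analyses, as are footprints whose A/P windows
#' overlap the stop codon or 3'UTR. Records of other lengths get `NA`
#' codons.
#'
#' @param rpf RPF table from [select_rpf()].
#' @param genes a `gene_set` carrying transcript sequences.
#' @param optimal_codons,non_optimal_codons character vectors used to
#'   flag codon optimality (`optimal` / `non_optimal` / `neutral`).
#' @return `rpf` with columns p_codon, a_codon, p_opt, a_opt, in_frame.
#' @export
assign_ap_codons <- function(rpf, genes,
                             optimal_codons = planted_codon_sets()$optimal,
                             non_optimal_codons = planted_codon_sets()$non_optimal) {
  n <- nrow(rpf)
  rpf$p_codon <- rpf$a_codon <- NA_character_
  rpf$p_opt <- rpf$a_opt <- NA_character_
  rpf$in_frame <- NA
  is29 <- which(rpf$length == 29L)
  if (length(is29)) {
    cds_len <- vapply(genes, `[[`, integer(1), "cds_len")[rpf$gene_id[is29]]
    tx <- vapply(genes, function(g) g$tx_seq %||% NA_character_,
                 character(1))[rpf$gene_id[is29]]
    p_start <- rpf$tpos5[is29] + 12L          # 0-based codon start
    in_frame <- p_start %% 3L == 0L
    ## the A-site codon (p_start+3 .. p_start+5) must stay within the
    ## coding codons upstream of the stop
    fits <- p_start + 6L <= cds_len - 3L
    ok <- in_frame & fits & !is.na(tx)
    rpf$in_frame[is29] <- in_frame
    rpf$p_codon[is29[ok]] <- substr(tx[ok], p_start[ok] + 1L, p_start[ok] + 3L)
    rpf$a_codon[is29[ok]] <- substr(tx[ok], p_start[ok] + 4L, p_start[ok] + 6L)
    flag <- function(codon) ifelse(is.na(codon), NA_character_,
                            ifelse(codon %in% optimal_codons, "optimal",
                            ifelse(codon %in% non_optimal_codons,
                                   "non_optimal", "neutral")))
    rpf$p_opt[is29] <- flag(rpf$p_codon[is29])
    rpf$a_opt[is29] <- flag(rpf$a_codon[is29])
  }
  rpf
}

#' Translation efficiency and TE bins
#'
#' `log2_te = log2(Ribo-seq TPM / RNA-seq TPM)` per gene. Genes whose
#' mRNA TPM falls below `tpm_floor` are excluded and reported via the
#' `excluded` attribute. Bins follow the cumulative thresholds
#' log2TE >= 3, >= 2, >= 1 and <= -1, <= -2, <= -3 (nested), with
#' `neutral` meaning |log2TE| <= `neutral_band`.
#'
#' @param ribo_tpm counts table with `tpm` for the Ribo-seq library
#'   (effective length = CDS).
#' @param rna_tpm counts table with `tpm` for the RNA-seq library
#'   (effective length = transcript).
#' @param tpm_floor minimum mRNA TPM (default 1).
#' @param neutral_band half-width of the neutral TE band (default 0.1).
#' @param cumulative if `FALSE`, bins are disjoint intervals
#'   `[1,2), [2,3), [3,Inf)` (and mirrored) instead of nested.
#' @return data frame gene_id, ribo_tpm, rna_tpm, log2_te, neutral, and
#'   logical bin columns ge1, ge2, ge3, le_m1, le_m2, le_m3.
#' @export
compute_te <- function(ribo_tpm, rna_tpm, tpm_floor = 1,
                       neutral_band = 0.1, cumulative = TRUE) {
  r <- setNames(ribo_tpm$tpm, ribo_tpm$gene_id)
  m <- setNames(rna_tpm$tpm, rna_tpm$gene_id)
  common <- intersect(names(r), names(m))
  keep <- common[m[common] >= tpm_floor]
  excluded <- setdiff(common, keep)
  log2_te <- log2(r[keep] / m[keep])
  ge <- function(t) if (cumulative) log2_te >= t
                    else log2_te >= t & log2_te < t + 1
  le <- function(t) if (cumulative) log2_te <= t
                    else log2_te <= t & log2_te > t - 1
  out <- data.frame(
    gene_id = keep, ribo_tpm = unname(r[keep]), rna_tpm = unname(m[keep]),
    log2_te = unname(log2_te),
    neutral = abs(log2_te) <= neutral_band,
    ge1 = ge(1), ge2 = ge(2), ge3 = log2_te >= 3,
    le_m1 = le(-1), le_m2 = le(-2), le_m3 = log2_te <= -3,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "excluded") <- excluded
  out
}
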