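## Codon-usage analytics: RSCU, differential RSCU, optimality calling,
## wobble-adjusted decoding capacity, and synonymous CDS optimization.

#' Relative synonymous codon usage of a gene set
#'
#' Codon counts are pooled across the set (stop codons excluded) and
#' `rscu_c = n_a * X_c / sum_{c' in a} X_{c'}` where `n_a` is the
#' synonymous family size. Families with zero pooled counts yield `NA`
#' and are listed in the `undefined` attribute. Per-gene averaging
#' (`pooled = FALSE`) computes RSCU per gene and averages across genes.
#'
#' @param cds character vector of in-frame CDS sequences.
#' @param pooled pool counts across the set (default) or average
#'   per-gene RSCU.
#' @return named numeric vector over the 61 sense codons, with
#'   attributes `counts` (pooled codon counts) and `undefined`.
#' @export
rscu <- function(cds, pooled = TRUE) {
  if (!length(cds)) stop2("rscu: empty gene set")
  fam <- codon_families()
  sense <- unlist(fam, use.names = FALSE)
  one <- function(counts) {
    out <- setNames(rep(NA_real_, length(sense)), sense)
    for (codons in fam) {
      tot <- sum(counts[codons])
      if (tot > 0) out[codons] <- length(codons) * counts[codons] / tot
    }
    out
  }
  count_codons <- function(s) {
    cod <- codon_split(s)
    tab <- table(factor(cod[cod %in% sense], sense))
    setNames(as.numeric(tab), sense)
  }
  if (pooled) {
    counts <- Reduce(`+`, lapply(cds, count_codons))
    out <- one(counts)
  } else {
    per <- lapply(cds, function(s) one(count_codons(s)))
    out <- setNames(rowMeans(do.call(cbind, per), na.rm = TRUE), sense)
    out[is.nan(out)] <- NA_real_
    counts <- Reduce(`+`, lapply(cds, count_codons))
  }
  out <- out[sort(names(out))]
  attr(out, "counts") <- counts[sort(names(counts))]
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}

#' Differential RSCU against a neutral-TE reference
#'
#' `delta_c = log2((rscu_bin_c + eps) / (rscu_neutral_c + eps))`,
#' computed over codons defined in both profiles; missing codons are
#' excluded and reported. Rows are ordered by decreasing bin RSCU.
#'
#' @param bin_profile RSCU profile of a TE bin ([rscu()]).
#' @param neutral_profile RSCU profile of the neutral-TE gene set.
#' @param eps pseudovalue guarding zero RSCU (default 0.01).
#' @return data frame codon, amino_acid, rscu_bin, rscu_neutral, delta,
#'   with attribute `excluded`.
#' @export
delta_rscu <- function(bin_profile, neutral_profile, eps = 0.01) {
  common <- intersect(names(bin_profile)[!is.na(bin_profile)],
                      names(neutral_profile)[!is.na(neutral_profile)])
  excluded <- setdiff(union(names(bin_profile), names(neutral_profile)),
                      common)
  gc <- Biostrings::GENETIC_CODE
  out <- data.frame(
    codon = common,
    amino_acid = unname(gc[common]),
    rscu_bin = unname(bin_profile[common]),
    rscu_neutral = unname(neutral_profile[common]),
    delta = log2((unname(bin_profile[common]) + eps) /
                   (unname(neutral_profile[common]) + eps)),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$rscu_bin), ]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Call optimal and non-optimal codons from a differential RSCU
#'
#' Codons enriched in the highly translated bin (`delta >= +t`) are
#' optimal; avoided codons (`delta <= -t`) are non-optimal; the rest are
#' neutral.
#'
#' @param delta data frame from [delta_rscu()] (computed against the
#'   highly translated TE bin).
#' @param threshold log2 threshold `t` (default 0.1).
#' @return list: `optimal`, `non_optimal` (character vectors of codons).
#' @export
call_optimal_codons <- function(delta, threshold = 0.1) {
  list(optimal = delta$codon[delta$delta >= threshold],
       non_optimal = delta$codon[delta$delta <= -threshold])
}

#' Default wobble pairing rules
#'
#' Allowed codon third-position bases per anticodon position-34 base
#' (DNA alphabet). Watson-Crick pairs are always allowed; the adjusted
#' set adds G34:U3, U34:G3, and treats A34 as inosine (reads U3, C3,
#' A3).
#'
#' @param adjusted include wobble extensions (default) or Watson-Crick
#'   only.
#' @return named list: anticodon-34 base -> codon third bases read.
#' @export
wobble_rules <- function(adjusted = TRUE) {
  if (adjusted)
    list(A = c("T", "C", "A"),    # A34 as inosine
         C = "G",
         G = c("C", "T"),         # G34 wobbles U3
         T = c("A", "G"))         # U34 wobbles G3
  else
    list(A = "T", C = "G", G = "C", T = "A")
}

#' Wobble-adjusted tRNA decoding capacity per codon
#'
#' `capacity(codon) = sum` of abundances of tRNAs whose anticodon
#' decodes the codon: anticodon positions 35-36 must Watson-Crick pair
#' the codon's first two bases, and the anticodon-34 base must read the
#' codon's third base under the supplied rules.
#'
#' @param trna data frame: anticodon (5'->3', DNA alphabet), abundance
#'   (copy number or TPM).
#' @param rules pairing rules from [wobble_rules()].
#' @return named numeric vector over the 61 sense codons; codons with no
#'   decoding tRNA get 0 and are listed in the `orphans` attribute.
#' @export
decoding_capacity <- function(trna, rules = wobble_rules()) {
  sense <- SENSE_CODONS()
  cap <- setNames(numeric(length(sense)), sense)
  anti_wc <- revcomp(sense)    # per-codon Watson-Crick anticodon
  first12 <- substr(anti_wc, 2L, 3L)   # anticodon 35-36 for this codon
  third <- substr(sense, 3L, 3L)
  for (i in seq_len(nrow(trna))) {
    ac <- trna$anticodon[i]
    ac34 <- substr(ac, 1L, 1L)
    reads3 <- rules[[ac34]]
    hit <- substr(ac, 2L, 3L) == first12 & third %in% reads3
    cap[hit] <- cap[hit] + trna$abundance[i]
  }
  attr(cap, "orphans") <- names(cap)[cap == 0]
  cap
}

#' Codon ranking from an RSCU profile
#'
#' @param profile RSCU profile ([rscu()]).
#' @return named character vector: amino acid -> highest-RSCU codon
#'   (alphabetical tie-break).
#' @export
codon_ranking <- function(profile) {
  fam <- codon_families()
  vapply(fam, function(codons) {
    v <- profile[codons]
    v[is.na(v)] <- -Inf
    codons[order(-v, codons)][1L]
  }, character(1))
}

#' Synonymous codon optimization of a CDS
#'
#' Every sense codon is replaced by the top-ranked codon of its amino
#' acid; the stop codon is left unchanged. The encoded protein and the
#' sequence length are preserved; the operation is idempotent.
#'
#' @param cds in-frame CDS string (single internal stop at the end).
#' @param ranking amino acid -> codon map (e.g. [codon_ranking()]).
#' @return optimized CDS string.
#' @export
optimize_cds <- function(cds, ranking) {
  cod <- codon_split(cds)
  aa <- Biostrings::GENETIC_CODE[cod]
  if (any(aa[-length(aa)] == "*"))
    stop2("optimize_cds: internal stop codon at codon ",
          which(aa[-length(aa)] == "*")[1L])
  if (any(is.na(aa))) stop2("optimize_cds: invalid codon in input")
  miss <- setdiff(unique(aa[aa != "*"]), names(ranking))
  if (length(miss))
    stop2("optimize_cds: ranking missing amino acid(s): ",
          paste(miss, collapse = ", "))
  sense <- aa != "*"
  cod[sense] <- unname(ranking[aa[sense]])
  paste(cod, collapse = "")
}
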