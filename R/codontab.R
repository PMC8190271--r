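## Codon bookkeeping shared by the simulator and the codon-usage module.

#' Sense codons and synonymous families
#'
#' Built from the standard genetic code (DNA alphabet). `codon_families()`
#' returns the list of synonymous families keyed by amino acid (stop
#' codons excluded).
#'
#' @return named list: amino acid -> character vector of codons.
#' @export
codon_families <- function() {
  gc <- Biostrings::GENETIC_CODE
  sense <- gc[gc != "*"]
  split(names(sense), sense)
}

SENSE_CODONS <- function() sort(unname(unlist(codon_families())))
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Default planted optimal / non-optimal codon sets
#'
#' For every amino acid with two or more synonymous codons, one codon is
#' declared optimal and one non-optimal, alternating which end of the
#' alphabetically sorted family is picked from one amino acid to the
#' next. The alternation balances third-position base composition
#' between the two sets, so codon optimality and local base content
#' (e.g. the template Cs where an RdRP can initiate) are decoupled in
#' the planted truth. Single-codon families (ATG, TGG) carry no
#' optimality signal. These are the simulator's planted truth, not an
#' empirical claim about any genome.
#'
#' @return list with character vectors `optimal` and `non_optimal`,
#'   named by amino acid.
#' @export
planted_codon_sets <- function() {
  fam <- codon_families()
  multi <- fam[lengths(fam) >= 2L]
  multi <- multi[order(names(multi))]
  flip <- seq_along(multi) %% 2L == 0L
  opt <- vapply(seq_along(multi), function(i) {
    x <- sort(multi[[i]])
    if (flip[i]) x[length(x)] else x[1L]
  }, character(1))
  non <- vapply(seq_along(multi), function(i) {
    x <- sort(multi[[i]])
    if (flip[i]) x[1L] else x[length(x)]
  }, character(1))
  list(optimal = setNames(opt, names(multi)),
       non_optimal = setNames(non, names(multi)))
}

#' Translate a CDS (character interface)
#' @param cds in-frame DNA string.
#' @return amino-acid string (stop as `*`).
#' @export
translate_cds <- function(cds) {
  paste(Biostrings::GENETIC_CODE[codon_split(cds)], collapse = "")
}
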