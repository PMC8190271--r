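#' @importFrom stats fft rbinom rlnorm rmultinom runif sd setNames phyper
#'   dhyper approx cor chisq.test median quantile
#' @importFrom utils read.delim write.table head tail
NULL

DNA <- c("A", "C", "G", "T")

#' Reverse-complement a character vector of DNA sequences
#'
#' @param x character vector over the DNA alphabet (ACGTN).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## complement of single bases, vectorised, no reversal
comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  vapply(len, function(l) paste(sample(DNA, l, replace = TRUE), collapse = ""),
         character(1))
}

#' Split an in-frame CDS string into codon triplets
#' @param seq DNA string whose length is a multiple of 3.
#' @return character vector of codons.
#' @export
codon_split <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3 == 0)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## sample from a value vector safely (no scalar-x expansion)
sample_vals <- function(x, n, prob = NULL) {
  x[sample.int(length(x), n, replace = TRUE, prob = prob)]
}

stop2 <- function(...) stop(..., call. = FALSE)
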