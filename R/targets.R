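## IP-defined small-RNA target calling, fold-changes, gene-set overlap
## enrichment, and gene-body metaprofiles.

#' Call IP-enriched small-RNA target genes
#'
#' A gene is a target when, in every IP replicate, its RPM is at least
#' `rpm_floor` and its IP/input enrichment at least `enrich_floor`.
#' Enrichment uses `rpm_ip / (rpm_input + eps)`; genes absent from the
#' input table get input RPM 0 (eps-guarded) and are flagged. Targets
#' are binned by mean IP RPM into [1,50), [50,150), [150,Inf).
#'
#' @param ip_rpm list of per-replicate named numeric vectors
#'   (gene -> RPM), or a single vector.
#' @param input_rpm named numeric vector (gene -> RPM); a list of
#'   per-replicate inputs is also accepted (matched to IP replicates by
#'   position).
#' @param rpm_floor minimum IP RPM per replicate (default 1).
#' @param enrich_floor minimum IP/input ratio per replicate (default 2).
#' @param eps input pseudovalue (default 0.25 RPM).
#' @return data frame: gene_id, mean_ip_rpm, min_enrichment, is_target,
#'   abundance_bin, input_missing.
#' @export
call_targets <- function(ip_rpm, input_rpm, rpm_floor = 1,
                         enrich_floor = 2, eps = 0.25) {
  if (!is.list(ip_rpm)) ip_rpm <- list(ip_rpm)
  per_rep_input <- is.list(input_rpm)
  if (per_rep_input && length(input_rpm) != length(ip_rpm))
    stop2("call_targets: per-replicate inputs must match IP replicates")
  genes <- sort(unique(unlist(lapply(ip_rpm, names))))
  ip_mat <- vapply(ip_rpm, function(v) {
    out <- v[genes]; out[is.na(out)] <- 0; out
  }, numeric(length(genes)))
  ip_mat <- matrix(ip_mat, nrow = length(genes))
  in_mat <- vapply(seq_along(ip_rpm), function(r) {
    v <- if (per_rep_input) input_rpm[[r]] else input_rpm
    out <- v[genes]; out[is.na(out)] <- 0; out
  }, numeric(length(genes)))
  in_mat <- matrix(in_mat, nrow = length(genes))
  input_missing <- if (per_rep_input)
    apply(vapply(seq_along(ip_rpm), function(r)
      !(genes %in% names(input_rpm[[r]])), logical(length(genes))), 1L, any)
  else !(genes %in% names(input_rpm))
  enrich <- ip_mat / (in_mat + eps)
  is_target <- apply(ip_mat >= rpm_floor & enrich >= enrich_floor, 1L, all)
  mean_ip <- rowMeans(ip_mat)
  bin <- rep(NA_character_, length(genes))
  bin[is_target & mean_ip >= 1 & mean_ip < 50] <- "[1,50)"
  bin[is_target & mean_ip >= 50 & mean_ip < 150] <- "[50,150)"
  bin[is_target & mean_ip >= 150] <- "[150,Inf)"
  data.frame(gene_id = genes, mean_ip_rpm = mean_ip,
             min_enrichment = apply(enrich, 1L, min),
             is_target = is_target, abundance_bin = bin,
             input_missing = input_missing,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene log2 fold change between two RPM tables
#'
#' `log2((rpm_a + pseudo) / (rpm_b + pseudo))` over the union of genes
#' (missing genes count as 0 RPM). Works equally on region-split tables.
#'
#' @param a,b named numeric vectors (gene -> RPM).
#' @param pseudo pseudocount (default 0.25).
#' @return named numeric vector of log2 ratios.
#' @export
fold_change <- function(a, b, pseudo = 0.25) {
  genes <- sort(union(names(a), names(b)))
  av <- a[genes]; av[is.na(av)] <- 0
  bv <- b[genes]; bv[is.na(bv)] <- 0
  setNames(log2((av + pseudo) / (bv + pseudo)), genes)
}

#' Gene-set overlap enrichment (exact hypergeometric)
#'
#' Representation factor `n_overlap * n_universe / (n_A * n_B)` (1 means
#' no enrichment) and the upper-tail exact hypergeometric probability
#' of observing at least the seen overlap.
#'
#' @param setA,setB character vectors of gene ids.
#' @param universe character vector containing both sets.
#' @return list: n_universe, n_setA, n_setB, n_overlap,
#'   representation_factor, p_value.
#' @export
overlap_enrichment <- function(setA, setB, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop2("overlap_enrichment: empty universe")
  setA <- unique(intersect(setA, universe))
  setB <- unique(intersect(setB, universe))
  N <- length(universe)
  k <- length(intersect(setA, setB))
  nA <- length(setA); nB <- length(setB)
  rf <- if (nA > 0 && nB > 0) k * N / (nA * nB) else NA_real_
  p <- phyper(k - 1L, nA, N - nA, nB, lower.tail = FALSE)
  list(n_universe = N, n_setA = nA, n_setB = nB, n_overlap = k,
       representation_factor = rf, p_value = p)
}

## rescale one coverage vector to n_bins by mean-within-bin; genes
## shorter than n_bins are linearly interpolated (flagged upstream)
rebin_coverage <- function(cov, n_bins) {
  L <- length(cov)
  if (L >= n_bins) {
    edges <- floor(seq(0L, L, length.out = n_bins + 1L))
    vapply(seq_len(n_bins), function(b)
      mean(cov[(edges[b] + 1L):edges[b + 1L]]), numeric(1))
  } else {
    approx(seq(0, 1, length.out = L), cov,
           xout = seq(0, 1, length.out = n_bins))$y
  }
}

#' Gene-body metaprofile (TSS to TES)
#'
#' Each gene's transcript-space coverage is rescaled to `n_bins` bins by
#' mean-within-bin (linear interpolation for genes shorter than
#' `n_bins`), then averaged across genes with equal weight; replicate
#' profiles are averaged afterwards.
#'
#' @param coverage named list: gene -> numeric coverage vector (e.g.
#'   RPM-scaled per-position coverage), or a list of such lists (one per
#'   replicate).
#' @param n_bins number of bins (default 100).
#' @return numeric vector of length `n_bins`, with attribute
#'   `interpolated` naming genes shorter than `n_bins`.
#' @export
metaprofile <- function(coverage, n_bins = 100L) {
  is_rep_list <- is.list(coverage) && length(coverage) &&
    is.list(coverage[[1L]])
  reps <- if (is_rep_list) coverage else list(coverage)
  interpolated <- character(0)
  prof_reps <- lapply(reps, function(covs) {
    if (!length(covs)) stop2("metaprofile: no genes")
    short <- names(covs)[lengths(covs) < n_bins]
    interpolated <<- union(interpolated, short)
    mats <- vapply(covs, rebin_coverage, numeric(n_bins), n_bins = n_bins)
    rowMeans(matrix(mats, nrow = n_bins))
  })
  out <- Reduce(`+`, prof_reps) / length(prof_reps)
  attr(out, "interpolated") <- interpolated
  out
}

#' Transcript-space coverage per gene from a hit table
#'
#' Full-read coverage (each read covers `length` nt from its 5' end,
#' mRNA-upstream for antisense reads) scaled by `per_million`.
#'
#' @param hits hit table.
#' @param genes a `gene_set`.
#' @param orientation optional orientation filter.
#' @param per_million scale factor applied to raw coverage (e.g. 1e6 /
#'   non-structural total); default 1.
#' @return named list gene -> numeric vector of length `tx_len`.
#' @export
coverage_by_gene <- function(hits, genes, orientation = NULL,
                             per_million = 1) {
  if (!is.null(orientation))
    hits <- hits[hits$orientation == orientation, , drop = FALSE]
  hits <- hits[hits$region != "outside", , drop = FALSE]
  out <- lapply(split(hits, hits$gene_id), function(part) {
    gene <- genes[[part$gene_id[1L]]]
    cov <- numeric(gene$tx_len)
    from <- ifelse(part$orientation == "sense", part$tpos5,
                   part$tpos5 - part$length + 1L)
    to <- from + part$length - 1L
    from <- pmax(from, 0L); to <- pmin(to, gene$tx_len - 1L)
    for (i in seq_len(nrow(part)))
      cov[(from[i] + 1L):(to[i] + 1L)] <- cov[(from[i] + 1L):(to[i] + 1L)] + 1
    cov * per_million
  })
  out
}
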