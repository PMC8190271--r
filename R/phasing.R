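## Distance distributions between RPF 5' starts and 22G 5' ends,
## z-scoring, and Fourier period detection.

#' Distance histogram between RPF and 22G 5' ends
#'
#' For every (sense RPF, antisense 22G) pair on the same gene the offset
#' `d = tpos5(22G) - tpos5(RPF)` is counted when `|d| <= window`.
#' Positive offsets are downstream of the footprint start on the mRNA.
#' Pairs are never formed across genes.
#'
#' @param rpf RPF table (gene_id, tpos5).
#' @param g22 antisense hit table (gene_id, tpos5), e.g. `G22` calls.
#' @param window half-width in nt (default 120).
#' @return `distance_series` data frame: offset (-window..window), count.
#' @export
distance_histogram <- function(rpf, g22, window = 120L) {
  if (!nrow(rpf) || !nrow(g22)) stop2("distance_histogram: no pairs")
  offsets <- seq(-window, window)
  counts <- numeric(length(offsets))
  shared <- intersect(unique(rpf$gene_id), unique(g22$gene_id))
  rs <- split(rpf$tpos5, rpf$gene_id)
  gs <- split(g22$tpos5, g22$gene_id)
  for (gid in shared) {
    r <- rs[[gid]]
    g <- gs[[gid]]
    span <- max(r, g) + 1L
    rt <- tabulate(r + 1L, nbins = span)
    gt <- tabulate(g + 1L, nbins = span)
    ## cross-correlation: counts[d] = sum_p rt[p] * gt[p + d]
    for (j in seq_along(offsets)) {
      d <- offsets[j]
      if (d >= 0L) {
        n <- span - d
        if (n > 0L) counts[j] <- counts[j] +
            sum(rt[seq_len(n)] * gt[seq_len(n) + d])
      } else {
        n <- span + d
        if (n > 0L) counts[j] <- counts[j] +
            sum(rt[seq_len(n) - d] * gt[seq_len(n)])
      }
    }
  }
  if (sum(counts) == 0) stop2("distance_histogram: no pairs within window")
  structure(data.frame(offset = offsets, count = counts),
            class = c("distance_series", "data.frame"))
}

#' z-score a distance series
#'
#' Population z-scores (mean 0, sd 1 with ddof = 0) over the full
#' window, the convention of scipy.stats.zscore.
#'
#' @param series `distance_series` with a `count` column.
#' @return the series with a `z` column added.
#' @export
zscore_series <- function(series) {
  x <- series$count
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  if (sdev == 0) stop2("zscore_series: degenerate histogram (sd = 0)")
  series$z <- (x - mu) / sdev
  series
}

#' Fourier periodogram of a z-scored distance series
#'
#' Discrete Fourier transform over the full window; power is the squared
#' magnitude, and frequencies are mapped to periods `N / k` for
#' `k = 1 .. floor(N/2)`. The DC component is excluded.
#'
#' @param series z-scored `distance_series`.
#' @return data frame: k, period, power.
#' @export
periodogram <- function(series) {
  z <- series$z
  if (is.null(z)) stop2("periodogram: z-score the series first")
  N <- length(z)
  ft <- fft(z)
  k <- seq_len(N %/% 2L)
  data.frame(k = k, period = N / k, power = Mod(ft[k + 1L])^2)
}

#' Dominant period of a periodogram
#'
#' The period of maximal power among periods inside `search_range`
#' (default 2-12 nt); exact power ties resolve to the smaller period.
#'
#' @param p data frame from [periodogram()].
#' @param search_range numeric `c(min, max)` period range.
#' @return the dominant period (numeric, `N / k`).
#' @export
dominant_period <- function(p, search_range = c(2, 12)) {
  cand <- p[p$period >= search_range[1L] & p$period <= search_range[2L], ]
  if (!nrow(cand)) stop2("dominant_period: empty search range")
  best <- which(cand$power == max(cand$power))
  min(cand$period[best])
}

#' Offset of maximal z within a reporting range
#'
#' @param series z-scored `distance_series`.
#' @param range numeric `c(lo, hi)` reporting range, default `(-15, 45)`.
#' @return list: offset, z.
#' @export
peak_offset <- function(series, range = c(-15L, 45L)) {
  sel <- series$offset > range[1L] & series$offset < range[2L]
  sub <- series[sel, ]
  i <- which.max(sub$z)
  list(offset = sub$offset[i], z = sub$z[i])
}

#' A/P-optimality-stratified phasing
#'
#' Restricts to 29-nt in-frame footprints, splits them into the
#' both-optimal and both-non-optimal A/P strata, and computes the
#' z-scored distance distribution of antisense 22G 5' ends per stratum,
#' reporting the offset of maximal z within the reporting range.
#'
#' @param rpf RPF table with codon columns ([assign_ap_codons()]).
#' @param g22 antisense 22G hit table (gene_id, tpos5).
#' @param window distance half-width (nt).
#' @param report_range reporting range for the peak, default `(-15, 45)`.
#' @param min_pairs strata with fewer counted pairs are flagged
#'   underpowered.
#' @return named list (`optimal`, `non_optimal`); each element has
#'   `series`, `n_pairs`, `underpowered`, `peak` (offset + z), or is
#'   `NULL` when the stratum is empty. Errors if both strata are empty.
#' @export
stratified_phasing <- function(rpf, g22, window = 120L,
                               report_range = c(-15L, 45L),
                               min_pairs = 1000L) {
  use <- rpf[rpf$length == 29L & !is.na(rpf$in_frame) & rpf$in_frame &
               !is.na(rpf$p_opt) & !is.na(rpf$a_opt), , drop = FALSE]
  strata <- list(
    optimal = use[use$p_opt == "optimal" & use$a_opt == "optimal", ],
    non_optimal = use[use$p_opt == "non_optimal" &
                        use$a_opt == "non_optimal", ])
  if (all(vapply(strata, nrow, integer(1)) == 0L))
    stop2("stratified_phasing: both strata empty")
  lapply(strata, function(part) {
    if (!nrow(part)) return(NULL)
    hist <- tryCatch(distance_histogram(part, g22, window),
                     error = function(e) NULL)
    if (is.null(hist)) return(NULL)
    series <- zscore_series(hist)
    n_pairs <- sum(series$count)
    list(series = series, n_pairs = n_pairs,
         underpowered = n_pairs < min_pairs,
         peak = peak_offset(series, report_range))
  })
}
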