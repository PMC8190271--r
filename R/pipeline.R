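## End-to-end synthetic walkthrough: simulate -> classify -> ribo ->
## phase -> codon -> targets, with one validated config and a
## machine-readable summary.

#' Default pipeline configuration
#'
#' A nested list: `sim` holds the [sim_config()] fields; the remaining
#' blocks hold each stage's tunables. Unknown keys anywhere are
#' rejected by [run_pipeline()].
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    sim = unclass(sim_config()),
    smallrna = list(len_window = c(21L, 23L)),
    riboprof = list(len_window = c(28L, 30L), tpm_floor = 1,
                    neutral_band = 0.1, cumulative = TRUE),
    phasing = list(window = 120L, report_range = c(-15L, 45L),
                   search_range = c(2, 12), min_pairs = 1000L),
    codon = list(eps = 0.01, threshold = 0.1, te_bin = "ge1"),
    targets = list(rpm_floor = 1, enrich_floor = 2, eps = 0.25)
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop2("run_pipeline: unknown config key",
          if (length(unknown) > 1) "s", " ",
          paste0(path, unknown, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.list(user[[nm]]))
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, nm, "$"))
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [default_config()]
#'   blocks; unknown keys are rejected at run time.
#' @return configuration list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' Run the full synthetic pipeline
#'
#' Simulates all libraries, classifies small RNAs (including the poly-U
#' rescue path on the raw input FASTQ), selects and codon-annotates
#' footprints, computes TE, phasing periodograms and the stratified
#' cleavage peak, recovers codon optimality from TE-binned differential
#' RSCU, and calls IP targets — then scores everything against the
#' planted truth. Identical seeds give identical summaries.
#'
#' @param config full or partial configuration (merged over
#'   [default_config()]); unknown keys raise a schema error before any
#'   stage runs.
#' @param outdir optional directory for per-stage outputs (TSVs plus
#'   `summary.json`).
#' @return summary list (also written as JSON when `outdir` is given).
#' @export
run_pipeline <- function(config = list(), outdir = NULL) {
  cfg <- merge_config(default_config(), config)
  sim_cfg <- do.call(sim_config, cfg$sim)

  stage <- function(name, expr) {
    message(sprintf("[phase22g] stage %-10s seed=%d", name, sim_cfg$seed))
    tryCatch(expr, error = function(e)
      stop2("stage '", name, "' failed: ", conditionMessage(e)))
  }

  libs <- stage("simulate", simulate_all(sim_cfg))
  sim <- libs$sim
  genes <- sim$genes
  truth <- sim$truth
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_sim(sim, libs, outdir)
  }

  ## --- small RNA classification + rescue ------------------------------
  srna <- stage("smallrna", {
    index <- toy_index(genes)
    per_lib <- lapply(c(list(libs$srna_input),
                        libs$srna_ip), function(lib) {
      hits <- project_reads(lib$reads, genes)
      reads <- lib$reads[match(hits$read_id, lib$reads$read_id), ]
      calls <- classify_small_rna(reads, hits, genes,
                                  cfg$smallrna$len_window)
      ## rescue path: tailed reads fail full-length exact mapping
      unmapped <- lib$fastq[lib$tail_len > 0L, , drop = FALSE]
      rescue <- rescue_polyU(unmapped, index, cfg$smallrna$len_window)
      list(calls = calls, rescue = rescue)
    })
    names(per_lib) <- c("srna_input",
                        sprintf("srna_ip_rep%d", seq_along(libs$srna_ip)))
    per_lib
  })

  ## --- ribo: RPF selection, codons, TE --------------------------------
  ribo <- stage("riboprof", {
    hits <- project_reads(libs$riboseq, genes)
    rpf <- select_rpf(hits, genes, cfg$riboprof$len_window)
    rpf <- assign_ap_codons(rpf, genes, sim_cfg$optimal_codons,
                            sim_cfg$non_optimal_codons)
    ## TPMs for TE are computed over non-structural genes only, the
    ## annotation practitioners quantify against (rRNA etc. excluded)
    coding <- genes[!is_structural(genes)]
    ribo_counts <- count_reads(hits[hits$orientation == "sense", ], coding)
    rna_hits <- project_reads(libs$rnaseq, genes)
    rna_counts <- count_reads(rna_hits[rna_hits$orientation == "sense", ],
                              coding)
    te <- compute_te(
      compute_tpm(ribo_counts, effective_lengths(coding, "cds")),
      compute_tpm(rna_counts, effective_lengths(coding, "transcript")),
      cfg$riboprof$tpm_floor, cfg$riboprof$neutral_band,
      cfg$riboprof$cumulative)
    list(rpf = rpf, te = te)
  })

  ## --- phasing --------------------------------------------------------
  g22 <- srna$srna_input$calls
  g22 <- g22[g22$sclass == "G22", ]
  phase <- stage("phasing", {
    series <- zscore_series(
      distance_histogram(ribo$rpf, g22, cfg$phasing$window))
    pg <- periodogram(series)
    strat <- stratified_phasing(ribo$rpf, g22, cfg$phasing$window,
                                cfg$phasing$report_range,
                                cfg$phasing$min_pairs)
    list(series = series, periodogram = pg,
         dominant_period = dominant_period(pg, cfg$phasing$search_range),
         strata = strat)
  })

  ## --- codon optimality recovery --------------------------------------
  codon <- stage("codon", {
    te <- ribo$te
    cds_of <- function(ids) vapply(ids, function(g)
      substr(genes[[g]]$tx_seq, 1L, genes[[g]]$cds_len), character(1))
    hi_ids <- te$gene_id[te[[cfg$codon$te_bin]]]
    neutral_ids <- te$gene_id[te$neutral]
    if (!length(hi_ids) || !length(neutral_ids))
      stop2("empty TE bin (", cfg$codon$te_bin, " or neutral)")
    d <- delta_rscu(rscu(cds_of(hi_ids)), rscu(cds_of(neutral_ids)),
                    cfg$codon$eps)
    calls <- call_optimal_codons(d, cfg$codon$threshold)
    jacc <- function(a, b)
      length(intersect(a, b)) / length(union(a, b))
    list(delta = d, calls = calls,
         jaccard_optimal = jacc(calls$optimal, sim_cfg$optimal_codons),
         jaccard_non_optimal = jacc(calls$non_optimal,
                                    sim_cfg$non_optimal_codons))
  })

  ## --- target calling vs truth ----------------------------------------
  targ <- stage("targets", {
    rpm_of <- function(calls) {
      g22c <- calls[calls$sclass == "G22", ]
      counts <- count_reads(
        data.frame(gene_id = g22c$gene_id, library_id = "lib",
                   region = g22c$region, orientation = g22c$orientation),
        genes)
      counts <- rpm_normalize(counts, genes)
      setNames(counts$rpm, counts$gene_id)
    }
    ip <- lapply(srna[startsWith(names(srna), "srna_ip")],
                 function(x) rpm_of(x$calls))
    input <- rpm_of(srna$srna_input$calls)
    called <- call_targets(ip, input, cfg$targets$rpm_floor,
                           cfg$targets$enrich_floor, cfg$targets$eps)
    tr <- truth[match(called$gene_id, truth$gene_id), ]
    keep <- !is.na(tr$gene_id)
    tp <- sum(called$is_target[keep] & tr$is_target[keep])
    fp <- sum(called$is_target[keep] & !tr$is_target[keep])
    fn <- sum(!called$is_target[keep] & tr$is_target[keep])
    list(calls = called,
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         fdr = if (tp + fp > 0) fp / (tp + fp) else 0)
  })

  te_sp <- cor(ribo$te$log2_te,
               log2(truth$te_true[match(ribo$te$gene_id, truth$gene_id)]),
               method = "spearman", use = "complete.obs")

  summary <- list(
    seed = sim_cfg$seed,
    n_genes = sim_cfg$n_genes,
    dominant_period = phase$dominant_period,
    max_z_offset = peak_offset(phase$series, cfg$phasing$report_range),
    strata = lapply(phase$strata, function(s)
      if (is.null(s)) NULL
      else list(peak_offset = s$peak$offset, peak_z = s$peak$z,
                n_pairs = s$n_pairs, underpowered = s$underpowered)),
    te_spearman = te_sp,
    codon_jaccard_optimal = codon$jaccard_optimal,
    codon_jaccard_non_optimal = codon$jaccard_non_optimal,
    target_sensitivity = targ$sensitivity,
    target_fdr = targ$fdr,
    rescue_stats = as.list(srna$srna_input$rescue$stats)
  )
  if (!is.null(outdir)) {
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.table(phase$series, file.path(outdir, "distance_series.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(phase$periodogram, file.path(outdir, "periodogram.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(codon$delta, file.path(outdir, "delta_rscu.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(targ$calls, file.path(outdir, "target_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(ribo$te, file.path(outdir, "te_table.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(summary = summary, libs = libs, srna = srna, ribo = ribo,
                 phase = phase, codon = codon, targets = targ))
}
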