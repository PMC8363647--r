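#' Pipeline configuration
#'
#' Bundles every tunable stage parameter of the end-to-end synthetic
#' analysis. Unknown parameter names are rejected.
#'
#' @param design a [sim_design()].
#' @param spec a [feature_spec()].
#' @param n_perm rank-product permutations (default 1000).
#' @param fc_threshold linear fold-change cut for significance (default 2).
#' @param pfp_threshold pfp cut, strict (default 0.2).
#' @param min_top_run TOP pyrimidine run length (default 4).
#' @param mfe_backend `"builtin"` or `"external"`.
#' @param go_terms,go_base_rate,go_enriched,go_enrich_factor synthetic GO
#'   map parameters (see [gen_go_map()]).
#' @param ... rejected; catches misspelled parameters.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(design = sim_design(), spec = feature_spec(),
                            n_perm = 1000, fc_threshold = 2,
                            pfp_threshold = 0.2, min_top_run = 4,
                            mfe_backend = "builtin", go_terms = 30,
                            go_base_rate = 0.05, go_enriched = 3,
                            go_enrich_factor = 3, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration keys: ", paste(names(extra), collapse = ", "))
  structure(list(design = design, spec = spec, n_perm = n_perm,
                 fc_threshold = fc_threshold, pfp_threshold = pfp_threshold,
                 min_top_run = min_top_run, mfe_backend = mfe_backend,
                 go_terms = go_terms, go_base_rate = go_base_rate,
                 go_enriched = go_enriched,
                 go_enrich_factor = go_enrich_factor),
            class = "pipeline_config")
}

#' Run the full synthetic translatome pipeline
#'
#' Simulates a two-colour polysome-profiling experiment and matched
#' transcripts, background-corrects and computes M-values, runs the
#' rank-product test, annotates UTR features, and tests feature and
#' GO-term enrichment of the UP list — writing every intermediate table
#' to `out_dir`. All randomness flows from the design seed, and outputs
#' contain no timestamps, so two runs with the same configuration are
#' byte-identical.
#'
#' @param out_dir output directory (created if missing).
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the in-memory results: `truth`,
#'   `mvalues`, `rankprod`, `significant`, `features`, `feature_enrichment`,
#'   `go`, and the vector of files written.
#' @export
run_pipeline <- function(out_dir, config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  design <- config$design
  path <- function(...) file.path(out_dir, ...)

  # --- simulate -------------------------------------------------------
  say("simulate: ", design$n_genes, " genes, ",
      design$n_tumour_samples, " tumour vs ", design$n_control_samples,
      " control samples x ", design$n_repeats, " repeats")
  truth <- plant_truth(design)
  sim <- gen_array_experiment(design, truth)
  tr <- gen_transcripts(design, config$spec, truth)
  go_map <- gen_go_map(truth, config$go_terms, config$go_base_rate,
                       config$go_enriched, config$go_enrich_factor,
                       seed = design$seed + 20011L)
  write_array_experiment(sim$experiment, path("intensities.tsv"),
                         path("array_metadata.tsv"))
  write_tsv(tr$truth, path("truth.tsv"))
  write_fasta(stats::setNames(tr$records$utr5, tr$records$gene_id), path("utr5.fa"))
  write_fasta(stats::setNames(tr$records$cds, tr$records$gene_id), path("cds.fa"))
  write_fasta(stats::setNames(tr$records$utr3, tr$records$gene_id), path("utr3.fa"))
  write_tsv(data.frame(gene = tr$records$gene_id,
                       utr5_len = nchar(tr$records$utr5),
                       cds_len = nchar(tr$records$cds),
                       utr3_len = nchar(tr$records$utr3)),
            path("regions.tsv"))
  write_gene_list(tr$tisu_list, path("tisu_genes.txt"))
  write_tsv(go_map, path("go_map.tsv"))

  # --- preprocess -----------------------------------------------------
  say("preprocess: normexp correction and M-values")
  mv <- compute_m_values(sim$experiment)
  write_matrix_tsv(mv$M, path("m_values.tsv"))

  # --- differential translation --------------------------------------
  say("difftrans: rank product, ", config$n_perm, " permutations")
  fc <- pairwise_fold_changes(mv)
  rp <- rank_product_test(fc, n_perm = config$n_perm, seed = design$seed)
  sig <- significant_genes(rp, config$fc_threshold, config$pfp_threshold)
  write_tsv(as.data.frame(rp), path("rankprod.tsv"))
  write_gene_list(sig$up, path("up_genes.txt"))
  write_gene_list(sig$down, path("down_genes.txt"))
  write_tsv(volcano_table(rp), path("volcano.tsv"))
  D <- pearson_distance_matrix(mv)
  write_matrix_tsv(D, path("pearson_distance.tsv"), id_col = "array")
  write_newick(cluster_arrays(mv), path("cluster.nwk"))

  # --- annotate -------------------------------------------------------
  say("annotate: UTR features (", config$mfe_backend, " folding backend)")
  feats <- annotate_transcripts(tr$records, tr$tisu_list,
                                min_top_run = config$min_top_run,
                                mfe_backend = config$mfe_backend)
  write_tsv(as.data.frame(feats), path("features.tsv"))

  # --- enrich ---------------------------------------------------------
  say("enrich: feature panel and GO over-representation on ",
      length(sig$up), " UP genes")
  fe <- if (length(sig$up) >= 2)
    feature_enrichment_panel(sig$up, feats) else NULL
  go <- if (length(sig$up) >= 1)
    go_overrepresentation(sig$up, truth$gene_id, go_map) else NULL
  if (!is.null(fe)) write_tsv(fe, path("feature_enrichment.tsv"))
  if (!is.null(go)) write_tsv(go, path("go_enrichment.tsv"))

  # --- summary and log ------------------------------------------------
  summary_df <- data.frame(
    quantity = c("n_genes", "n_arrays", "n_up", "n_down"),
    value = c(design$n_genes, nrow(mv$metadata),
              length(sig$up), length(sig$down)))
  write_tsv(summary_df, path("summary.tsv"))
  log_lines <- c(
    "polyprof run log",
    sprintf("seed: %d", design$seed),
    sprintf("design: %d genes, %d tumour x %d control samples, %d repeats",
            design$n_genes, design$n_tumour_samples,
            design$n_control_samples, design$n_repeats),
    sprintf("planted: frac_up=%.3f frac_down=%.3f effect_log2=%.2f noise_sd=%.2f",
            design$frac_up, design$frac_down, design$effect_log2,
            design$noise_sd),
    sprintf("rankprod: n_perm=%d fc_threshold=%.2f pfp_threshold=%.2f",
            config$n_perm, config$fc_threshold, config$pfp_threshold),
    sprintf("result: %d UP, %d DOWN", length(sig$up), length(sig$down)))
  writeLines(log_lines, path("run_log.txt"))
  files <- list.files(out_dir)
  say("done: ", length(files), " files in ", out_dir)
  invisible(list(truth = truth, mvalues = mv, rankprod = rp,
                 significant = sig, features = feats,
                 feature_enrichment = fe, go = go, files = files))
}
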