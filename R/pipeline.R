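#' Analysis thresholds
#'
#' The operating points used across the pipeline, collected in one place.
#'
#' @param cs_threshold Coherence score pass threshold (default 0.18).
#' @param jaccard_threshold Redundancy filter threshold (default 0.25).
#' @param marker_fc Single-cell marker fold-change threshold (default 2).
#' @param marker_p Single-cell marker P-value threshold (default 1e-10).
#' @param subtype_log2fc Subtype derivation log2 fold-change threshold
#'   (default 2).
#' @param subtype_adj_p Subtype derivation adjusted-P threshold
#'   (default 0.05).
#' @return A list of class `AnalysisThresholds`.
#' @export
analysis_thresholds <- function(cs_threshold = 0.18, jaccard_threshold = 0.25,
                                marker_fc = 2, marker_p = 1e-10,
                                subtype_log2fc = 2, subtype_adj_p = 0.05) {
  vals <- c(cs_threshold, jaccard_threshold, marker_fc, marker_p,
            subtype_log2fc, subtype_adj_p)
  if (any(vals <= 0)) stop("all thresholds must be positive", call. = FALSE)
  if (cs_threshold >= 1) stop("cs_threshold must be in (0, 1)", call. = FALSE)
  structure(list(cs_threshold = cs_threshold,
                 jaccard_threshold = jaccard_threshold,
                 marker_fc = marker_fc, marker_p = marker_p,
                 subtype_log2fc = subtype_log2fc,
                 subtype_adj_p = subtype_adj_p),
            class = "AnalysisThresholds")
}

#' Random control signatures for a coherence screen
#'
#' Gene sets drawn uniformly from the universe (minus excluded genes, e.g.
#' planted program genes), carrying no co-regulation: negative controls
#' expected to fail the coherence filter.
#'
#' @param gene_ids Gene universe to draw from.
#' @param exclude Genes never drawn (default none).
#' @param n_sigs Number of control signatures (default 10).
#' @param set_size Genes per signature (default 30).
#' @param seed Integer seed.
#' @return A [signature_collection()].
#' @export
random_control_signatures <- function(gene_ids, exclude = character(),
                                      n_sigs = 10, set_size = 30, seed = 1L) {
  pool <- setdiff(gene_ids, exclude)
  withr::with_seed(seed, {
    signature_collection(lapply(seq_len(n_sigs), function(i) {
      gene_signature(sprintf("random_control_%02d", i),
                     pool[sample.int(length(pool), set_size)],
                     category = "other", source = "random control set")
    }))
  })
}

#' Run the full synthetic end-to-end pipeline
#'
#' Reproduces the study design on synthetic data with known ground truth:
#' simulate a single-cell cohort with planted stromal and malignant
#' programs; score the programs per cell and attribute them to cell types;
#' find fibroblast-vs-malignant markers and the per-signature DEG
#' percentages; mix pseudobulk samples along a fibroblast gradient and
#' verify that the EMT-like bulk score tracks the fibroblast fraction;
#' simulate a bulk cohort with known purity, screen signatures by coherence
#' score, and test the score-purity associations across purity strata and
#' NAT samples; finally derive a subtype proxy gene set from a labeled
#' cohort. All result tables are written as TSV under `out_dir`, plus a
#' `manifest.json` recording seeds, thresholds and stage summaries. Given
#' the same seed, two runs write byte-identical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; per-stage seeds are derived from it.
#' @param thresholds An [analysis_thresholds()].
#' @param module_cfg A [module_score_config()] (its seed is overridden by
#'   `seed`).
#' @param sc_cfg,bulk_cfg,subtype_cfg Optional generator configs; defaults
#'   are the study conditions (seeds overridden by `seed`).
#' @param design A [pseudobulk_design()] (seed overridden by `seed`).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the main in-memory results and
#'   `out_dir`.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         thresholds = analysis_thresholds(),
                         module_cfg = module_score_config(),
                         sc_cfg = NULL, bulk_cfg = NULL, subtype_cfg = NULL,
                         design = NULL, quiet = FALSE) {
  seed <- as.integer(seed)
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(sc_cfg)) sc_cfg <- cell_program_config(seed = seed)
  if (is.null(bulk_cfg)) {
    bulk_cfg <- bulk_cohort_config(program = cell_program_config(seed = seed),
                                   seed = seed + 1L)
  }
  if (is.null(subtype_cfg)) subtype_cfg <- subtype_cohort_config(seed = seed + 2L)
  if (is.null(design)) design <- pseudobulk_design(seed = seed + 3L)
  module_cfg$seed <- seed + 4L

  # -- stage 1: single-cell simulation and per-cell attribution ---------------
  sc <- generate_single_cell(sc_cfg)
  say("simulated %d genes x %d cells (%d cell types)",
      nrow(sc$expr$values), ncol(sc$expr$values),
      length(unique(sc$annotation$cell_type)))
  lognorm <- log_transform(counts_per_10k(sc$expr))
  dot_rows <- list()
  for (s in sc$truth$signatures) {
    ms <- score_single_cell(lognorm, s, module_cfg)
    d <- celltype_dot_stats(ms, sc$annotation)
    d$signature <- s$name
    dot_rows[[s$name]] <- d
  }
  dot_stats <- do.call(rbind, dot_rows)
  dot_stats <- dot_stats[, c("signature", setdiff(names(dot_stats), "signature"))]
  write_table(dot_stats, file.path(out_dir, "celltype_dot_stats.tsv"))

  de <- find_markers(lognorm, sc$annotation, "fibroblast", "malignant",
                     fc = thresholds$marker_fc, p = thresholds$marker_p)
  say("markers fibroblast vs malignant: %d up in fibroblast, %d up in malignant",
      sum(de$passed_in_group1), sum(de$passed_in_group2))
  write_table(de, file.path(out_dir, "markers_fibroblast_vs_malignant.tsv"))
  deg_frac <- signature_deg_fractions(de, sc$truth$signatures)
  write_table(deg_frac, file.path(out_dir, "signature_deg_fractions.tsv"))

  # -- stage 2: pseudobulk fibroblast gradient --------------------------------
  pb <- make_pseudobulk(sc$expr, sc$annotation, design)
  pb_tpm <- length_normalized_tpm(pb$expr)
  pb_scores <- score_bulk_collection(pb_tpm, sc$truth$signatures)
  write_table(pb_scores, file.path(out_dir, "pseudobulk_scores.tsv"))
  pb_assoc <- data.frame(
    signature = rownames(pb_scores$values),
    spearman_vs_fibroblast_fraction = apply(pb_scores$values, 1, function(v)
      stats::cor(v, pb$fractions$fibroblast_fraction, method = "spearman")),
    stringsAsFactors = FALSE, row.names = NULL)
  write_table(pb_assoc, file.path(out_dir, "pseudobulk_association.tsv"))
  say("pseudobulk: Spearman(EMT-like score, fibroblast fraction) = %.3f",
      pb_assoc$spearman_vs_fibroblast_fraction[
        pb_assoc$signature == "emt_like"])

  # -- stage 3: bulk cohort, coherence screen, purity association -------------
  bulk <- generate_bulk_cohort(bulk_cfg)
  bulk_tpm <- length_normalized_tpm(bulk$expr)
  coll <- signature_collection(c(unclass(bulk$truth$signatures),
                                 unclass(random_control_signatures(
                                   em_genes(bulk$expr),
                                   unlist(lapply(bulk$truth$signatures,
                                                 `[[`, "genes")),
                                   seed = seed + 5L))))
  coll <- filter_redundant(coll, threshold = thresholds$jaccard_threshold)
  tumor_tpm <- em_subset(bulk_tpm, columns = names(bulk$nat)[!bulk$nat])
  cs_report <- coherence_report(tumor_tpm, coll,
                                threshold = thresholds$cs_threshold,
                                n_draws = 1000, seed = seed + 6L)
  write_table(cs_report, file.path(out_dir, "coherence_report.tsv"))
  coherent <- filter_coherent(cs_report, coll,
                              threshold = thresholds$cs_threshold)
  say("coherence screen: %d of %d signatures pass CS > %.2f",
      length(coherent), length(coll), thresholds$cs_threshold)
  scores <- score_bulk_collection(bulk_tpm, coherent)
  write_table(scores, file.path(out_dir, "bulk_scores.tsv"))
  tumor_purity <- bulk$purity[!bulk$nat[bulk$purity$sample_id], , drop = FALSE]
  r_table <- correlate_scores(scores, tumor_purity)
  write_table(r_table, file.path(out_dir, "score_purity_correlation.tsv"))
  groups <- purity_groups(bulk$purity, nat = bulk$nat)
  cmp <- compare_groups(scores, groups, pairing = bulk$pairing)
  write_table(cmp, file.path(out_dir, "group_comparisons.tsv"))
  say("purity association: r(emt_like, purity) = %.3f",
      r_table$r[r_table$signature == "emt_like"])

  # -- stage 4: subtype proxy derivation --------------------------------------
  sub <- generate_subtype_cohort(subtype_cfg)
  target <- names(subtype_cfg$planted)[1]
  der <- derive_subtype_signature(sub$truth$candidates, sub$expr, sub$labels,
                                  target_label = target,
                                  log2fc = thresholds$subtype_log2fc,
                                  adj_p = thresholds$subtype_adj_p)
  write_table(der$stats, file.path(out_dir, "subtype_derivation.tsv"))
  if (!is.null(der$signature)) {
    write_gmt(signature_collection(der$signature),
              file.path(out_dir, "subtype_proxy.gmt"))
  }
  say("subtype proxy: %d of %d candidates kept", length(der$genes),
      der$n_tested)

  manifest <- list(
    package = "stromasig",
    seed = seed,
    thresholds = unclass(thresholds),
    module_score = list(n_bins = module_cfg$n_bins, n_ctrl = module_cfg$n_ctrl,
                        seed = module_cfg$seed),
    stages = list(
      single_cell = list(n_genes = nrow(sc$expr$values),
                         n_cells = ncol(sc$expr$values),
                         markers_up_fibroblast = sum(de$passed_in_group1),
                         markers_up_malignant = sum(de$passed_in_group2)),
      pseudobulk = list(n_samples = design$n_samples,
                        fraction_range = design$fraction_range,
                        cells_per_sample = design$cells_per_sample),
      bulk = list(n_samples = bulk_cfg$n_samples, n_nat = bulk_cfg$n_nat,
                  n_signatures_screened = length(coll),
                  n_signatures_coherent = length(coherent)),
      subtype = list(target = target, n_tested = der$n_tested,
                     n_kept = length(der$genes))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(out_dir = out_dir, dot_stats = dot_stats, de = de,
                 deg_fractions = deg_frac, pseudobulk_association = pb_assoc,
                 coherence_report = cs_report, score_purity = r_table,
                 group_comparisons = cmp, subtype = der))
}
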