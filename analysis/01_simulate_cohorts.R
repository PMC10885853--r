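#!/usr/bin/env Rscript
# Simulate the study's synthetic cohorts and record their design summaries.
#
# Four datasets with known ground truth stand in for consortium data:
#   - a single-cell cohort (5 cell types) with an EMT-like program planted
#     on fibroblasts/myofibroblasts and a proliferation-like program on
#     malignant cells;
#   - a 20-sample pseudobulk cohort mixing fibroblast and malignant cells
#     along a 20%-80% fibroblast gradient;
#   - a 100-sample bulk cohort with known purity plus 20 paired NAT samples;
#   - a subtype-labeled cohort (CMS1-4) with 10 planted CMS4-up genes.
# All later analysis scripts regenerate these deterministically from the
# same seed rather than reading large intermediate matrices from disk.

suppressPackageStartupMessages(library(stromasig))
seed <- 1L
dir.create("results", showWarnings = FALSE)

prog <- cell_program_config(seed = seed)
sc <- generate_single_cell(prog)
cat(sprintf("single-cell cohort: %d genes x %d cells\n",
            nrow(sc$expr$values), ncol(sc$expr$values)))
print(table(sc$annotation$cell_type))

pb <- make_pseudobulk(sc$expr, sc$annotation,
                      pseudobulk_design(seed = seed + 3L))
cat(sprintf("\npseudobulk cohort: %d samples, fibroblast fraction %.2f-%.2f\n",
            nrow(pb$fractions), min(pb$fractions$fibroblast_fraction),
            max(pb$fractions$fibroblast_fraction)))

bulk <- generate_bulk_cohort(bulk_cohort_config(program = prog,
                                                seed = seed + 1L))
tumor_purity <- bulk$purity$purity[!bulk$nat[bulk$purity$sample_id]]
cat(sprintf("\nbulk cohort: %d tumor + %d NAT samples; tumor purity %.2f-%.2f (median %.2f)\n",
            sum(!bulk$nat), sum(bulk$nat), min(tumor_purity),
            max(tumor_purity), median(tumor_purity)))

sub <- generate_subtype_cohort(subtype_cohort_config(seed = seed + 2L))
cat("\nsubtype cohort samples per label:\n")
print(table(sub$labels))

summary_tbl <- data.frame(
  dataset = c("single_cell", "pseudobulk", "bulk", "subtype"),
  n_genes = c(nrow(sc$expr$values), nrow(pb$expr$values),
              nrow(bulk$expr$values), nrow(sub$expr$values)),
  n_columns = c(ncol(sc$expr$values), ncol(pb$expr$values),
                ncol(bulk$expr$values), ncol(sub$expr$values)),
  seed = c(seed, seed + 3L, seed + 1L, seed + 2L))
write_table(summary_tbl, "results/cohort_summary.tsv")
write_table(pb$fractions, "results/pseudobulk_fractions.tsv")
write_table(as.data.frame(bulk$purity), "results/bulk_purity.tsv")
cat("\nwrote results/cohort_summary.tsv, results/pseudobulk_fractions.tsv, results/bulk_purity.tsv\n")
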