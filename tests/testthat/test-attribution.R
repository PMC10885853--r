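fixture_sc <- function(seed = 30) {
  generate_single_cell(cell_program_config(
    n_genes = 400,
    cells_per_type = c(malignant = 200, fibroblast = 200),
    planted_signatures = list(
      fib_prog = list(n_genes = 15, loading = 3, cell_types = "fibroblast",
                      category = "EMT"),
      mal_prog = list(n_genes = 15, loading = 3, cell_types = "malignant",
                      category = "process")),
    seed = seed))
}

test_that("rank-sum marker test matches wilcox.test and flags planted genes", {
  sc <- fixture_sc()
  ln <- log_transform(counts_per_10k(sc$expr))
  de <- find_markers(ln, sc$annotation, "fibroblast", "malignant")

  # agreement with the reference implementation on a handful of genes
  fib <- sc$annotation$cell_id[sc$annotation$cell_type == "fibroblast"]
  mal <- sc$annotation$cell_id[sc$annotation$cell_type == "malignant"]
  for (g in rownames(ln$values)[c(1, 50, 200, 400)]) {
    ref <- suppressWarnings(
      wilcox.test(ln$values[g, fib], ln$values[g, mal], exact = FALSE))
    expect_equal(de$p_value[de$gene == g], ref$p.value, tolerance = 1e-9)
  }

  planted <- sc$truth$signatures[["fib_prog"]]$genes
  expect_gte(mean(de$passed_in_group1[de$gene %in% planted]), 0.8)
  expect_false(any(de$passed_in_group2[de$gene %in% planted]))

  # identical groups produce no passing gene
  half1 <- fib[1:100]; half2 <- fib[101:200]
  ann_split <- cell_annotation(c(half1, half2),
                               rep(c("fibroblast", "malignant"), each = 100))
  ln_fib <- em_subset(ln, columns = c(half1, half2))
  de_null <- find_markers(ln_fib, ann_split, "fibroblast", "malignant")
  expect_equal(sum(de_null$passed_in_group1) + sum(de_null$passed_in_group2), 0)

  expect_error(find_markers(ln, sc$annotation, "endothelial", "malignant"),
               ">= 3 cells")
})

test_that("marker testing is symmetric under group swap", {
  sc <- fixture_sc(seed = 31)
  ln <- log_transform(counts_per_10k(sc$expr))
  de_fm <- find_markers(ln, sc$annotation, "fibroblast", "malignant")
  de_mf <- find_markers(ln, sc$annotation, "malignant", "fibroblast")
  expect_equal(de_fm$log2fc, -de_mf$log2fc, tolerance = 1e-12)
  expect_equal(de_fm$p_value, de_mf$p_value, tolerance = 1e-12)
  expect_identical(de_fm$passed_in_group1, de_mf$passed_in_group2)
  expect_identical(de_fm$passed_in_group2, de_mf$passed_in_group1)
})

test_that("the inclusive fold-change boundary is honored", {
  # construct log-normalized values with an exact de-logged ratio of 2
  n <- 50
  v1 <- rep(log2(9 + 1), n)   # de-log mean 9, +1 -> 10
  v2 <- rep(log2(4 + 1), n)   # de-log mean 4, +1 -> 5; ratio exactly 2
  m <- rbind(gene_boundary = c(v1, v2),
             gene_filler1 = c(rep(1, n), rep(1.2, n)),
             gene_filler2 = c(rep(2, n), rep(1.8, n)))
  colnames(m) <- sprintf("c%03d", seq_len(2 * n))
  ann <- cell_annotation(colnames(m),
                         rep(c("fibroblast", "malignant"), each = n))
  de <- find_markers(make_em(m, layer = "log_norm"), ann,
                     "fibroblast", "malignant", fc = 2, p = 1e-10)
  row <- de[de$gene == "gene_boundary", ]
  expect_equal(row$log2fc, 1, tolerance = 1e-12)
  expect_true(row$p_value < 1e-10)   # complete separation at n = 50/50
  expect_true(row$passed_in_group1)
})

test_that("signature DEG percentages count passed genes over available genes", {
  de <- data.frame(
    gene = sprintf("g%02d", 1:10),
    log2fc = c(rep(2, 4), rep(0, 5), -2.5),
    p_value = c(rep(1e-15, 4), rep(0.5, 5), 1e-15),
    passed_in_group1 = c(rep(TRUE, 4), rep(FALSE, 6)),
    passed_in_group2 = c(rep(FALSE, 9), TRUE))
  class(de) <- c("DEResult", "data.frame")
  attr(de, "group1") <- "fibroblast"; attr(de, "group2") <- "malignant"
  coll <- signature_collection(list(
    gene_signature("ten", sprintf("g%02d", 1:10)),
    gene_signature("all_passed", sprintf("g%02d", 1:4)),
    gene_signature("absent", c("x1", "x2"))))
  out <- signature_deg_fractions(de, coll)
  expect_equal(out$pct_group1[out$signature == "ten"], 40)
  expect_equal(out$pct_group2[out$signature == "ten"], 10)
  expect_equal(out$pct_group1[out$signature == "all_passed"], 100)
  expect_equal(out$pct_group2[out$signature == "all_passed"], 0)
  expect_false(out$defined[out$signature == "absent"])

  # multi-dataset pooling by union of availability and passes
  de2 <- de
  de2$gene <- sprintf("g%02d", 6:15)
  de2$passed_in_group1 <- c(TRUE, rep(FALSE, 9))
  out2 <- signature_deg_fractions(list(de, de2), coll)
  expect_equal(out2$n_available[out2$signature == "ten"], 10)
  expect_equal(out2$pct_group1[out2$signature == "ten"], 50)  # g06 added
})

test_that("planted fibroblast and malignant programs attribute correctly", {
  sc <- fixture_sc(seed = 32)
  ln <- log_transform(counts_per_10k(sc$expr))
  de <- find_markers(ln, sc$annotation, "fibroblast", "malignant")
  out <- signature_deg_fractions(de, sc$truth$signatures)
  expect_gte(out$pct_group1[out$signature == "fib_prog"], 80)
  expect_lte(out$pct_group2[out$signature == "fib_prog"], 5)
  expect_lte(out$pct_group1[out$signature == "mal_prog"], 5)
  expect_gte(out$pct_group2[out$signature == "mal_prog"], 80)
})

test_that("dot statistics summarize per-type means and positive fractions", {
  ann <- cell_annotation(sprintf("c%d", 1:6),
                         c("malignant", "malignant", "fibroblast",
                           "fibroblast", "fibroblast", "endothelial"))
  scores <- setNames(c(0, 0, 1.5, -0.5, 2.5, 0), sprintf("c%d", 1:6))
  out <- celltype_dot_stats(scores, ann)
  expect_equal(out$mean_score[out$cell_type == "malignant"], 0)
  expect_equal(out$fraction_positive[out$cell_type == "malignant"], 0)
  expect_equal(out$mean_score[out$cell_type == "fibroblast"], mean(c(1.5, -0.5, 2.5)))
  expect_equal(out$fraction_positive[out$cell_type == "fibroblast"], 2 / 3)
  expect_false(out$available[out$cell_type == "immune"])  # no cells: flagged

  sc <- fixture_sc(seed = 33)
  ln <- log_transform(counts_per_10k(sc$expr))
  ms <- score_single_cell(ln, sc$truth$signatures[["fib_prog"]],
                          module_score_config(seed = 40))
  dots <- celltype_dot_stats(ms, sc$annotation)
  expect_gt(dots$mean_score[dots$cell_type == "fibroblast"],
            dots$mean_score[dots$cell_type == "malignant"])
})

test_that("the gene triple table links bulk profiles, purity, and sc markers", {
  prog <- cell_program_config(seed = 34)
  bulk <- generate_bulk_cohort(bulk_cohort_config(n_samples = 60, n_nat = 0,
                                                  program = prog, seed = 34))
  tpm <- length_normalized_tpm(bulk$expr)
  sig <- bulk$truth$signatures[["emt_like"]]
  scores <- score_bulk_collection(tpm, bulk$truth$signatures)

  # matched synthetic single-cell data from the same program truth
  sc <- generate_single_cell(prog)
  ln <- log_transform(counts_per_10k(sc$expr))
  de <- find_markers(ln, sc$annotation, "fibroblast", "malignant")

  out <- gene_triple_table(tpm, bulk$purity, scores, sig, de)
  expect_equal(sort(out$gene), sort(sig$genes))
  # per-gene correlations are attenuated by the cohort's per-gene NB noise
  # (dispersion 0.05 caps single-gene |r| near 0.85), so the medians sit a
  # little below the signature-level correlations
  expect_lte(median(out$r_gene_vs_purity), -0.7)
  expect_gte(mean(out$fibroblast_dominant), 0.9)
  expect_gt(median(out$r_gene_vs_score), 0.7)

  # dominant genes sit lower on the purity axis than non-dominant genes
  all_de_genes <- de$gene
  mixed_sig <- gene_signature("mixed", c(sig$genes,
                                         sc$truth$signatures[["proliferation_like"]]$genes))
  scores_mixed <- score_bulk_collection(tpm, signature_collection(mixed_sig))
  out_mixed <- gene_triple_table(tpm, bulk$purity, scores_mixed, mixed_sig, de)
  expect_lt(median(out_mixed$r_gene_vs_purity[out_mixed$fibroblast_dominant]),
            median(out_mixed$r_gene_vs_purity[!out_mixed$fibroblast_dominant]))

  # a gene equal to the score vector correlates perfectly with it
  m <- rbind(gs = as.numeric(scores$values["emt_like", ]) + 1)
  colnames(m) <- colnames(scores$values)
  em1 <- make_em(rbind(m, other1 = runif(ncol(m)), other2 = runif(ncol(m))),
                 layer = "tmm_tpm")
  sig1 <- gene_signature("emt_like", c("gs", "missing_gene"))
  sm1 <- score_matrix(scores$values["emt_like", , drop = FALSE], "tmm_tpm")
  expect_warning(out1 <- gene_triple_table(em1, bulk$purity, sm1, sig1, de),
                 "absent")
  expect_equal(out1$r_gene_vs_score[out1$gene == "gs"], 1, tolerance = 1e-12)
})
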