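sc_small <- function(seed = 1, ...) {
  cell_program_config(n_genes = 300,
                      cells_per_type = c(malignant = 150, fibroblast = 150),
                      planted_signatures = list(
                        emt_like = list(n_genes = 20, loading = 2.5,
                                        cell_types = "fibroblast",
                                        category = "EMT")),
                      seed = seed, ...)
}

test_that("single-cell generation is deterministic and truth round-trips", {
  a <- generate_single_cell(sc_small())
  b <- generate_single_cell(sc_small())
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$annotation$cell_type, b$annotation$cell_type)

  # every planted gene and loading is recoverable from the truth tables
  sig <- a$truth$signatures[["emt_like"]]
  expect_length(sig$genes, 20)
  expect_true(all(a$truth$loadings[sig$genes, "fibroblast"] == 2.5))
  expect_true(all(a$truth$loadings[setdiff(rownames(a$truth$loadings),
                                           sig$genes), ] == 0))
  expect_equal(sort(unique(a$annotation$cell_type)),
               c("fibroblast", "malignant"))
  expect_equal(a$expr$layer, "counts")
})

test_that("planted loadings appear as the expected fold change in means", {
  sc <- generate_single_cell(cell_program_config(
    n_genes = 500,
    cells_per_type = c(malignant = 500, fibroblast = 500),
    planted_signatures = list(
      emt_like = list(n_genes = 30, loading = 2.5, cell_types = "fibroblast",
                      category = "EMT")),
    seed = 2))
  ann <- sc$annotation
  fib <- ann$cell_id[ann$cell_type == "fibroblast"]
  mal <- ann$cell_id[ann$cell_type == "malignant"]
  genes <- sc$truth$signatures[["emt_like"]]$genes
  ratio <- rowMeans(sc$expr$values[genes, fib]) /
    rowMeans(sc$expr$values[genes, mal])
  # expected ratio 2^2.5 ~ 5.66; bulk of genes must land in [4, 8]
  expect_gt(median(ratio), 4)
  expect_lt(median(ratio), 8)
})

test_that("zero loadings give cell types with statistically equal means", {
  sc <- generate_single_cell(cell_program_config(
    n_genes = 200, cells_per_type = c(malignant = 500, fibroblast = 500),
    planted_signatures = list(), seed = 3))
  ann <- sc$annotation
  fib <- ann$cell_id[ann$cell_type == "fibroblast"]
  mal <- ann$cell_id[ann$cell_type == "malignant"]
  pvals <- apply(sc$expr$values, 1, function(v) {
    tryCatch(t.test(v[fib], v[mal])$p.value, error = function(e) 1)
  })
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("pseudobulk uses the fraction grid and sums sampled cell counts", {
  sc <- generate_single_cell(sc_small())
  des <- pseudobulk_design(n_samples = 20, cells_per_sample = 200, seed = 5)
  pb <- make_pseudobulk(sc$expr, sc$annotation, des)
  expect_equal(pb$fractions$fibroblast_fraction,
               seq(0.2, 0.8, length.out = 20))
  expect_equal(pb$purity$purity, 1 - seq(0.2, 0.8, length.out = 20))
  expect_equal(attr(pb$purity, "method"), "simulated_truth")
  # column sums are sums of individual cells' totals: all counts integral
  expect_true(all(pb$expr$values == round(pb$expr$values)))

  # pure-fibroblast design: pseudobulk library is a sum of fibroblast cells
  des1 <- pseudobulk_design(n_samples = 1, fraction_range = c(1, 1),
                            cells_per_sample = 50, seed = 6)
  pb1 <- make_pseudobulk(sc$expr, sc$annotation, des1)
  fib_cells <- sc$annotation$cell_id[sc$annotation$cell_type == "fibroblast"]
  fib_max <- max(sc$expr$values[, fib_cells]) * 50
  expect_true(all(pb1$expr$values <= fib_max))
  genes <- sc$truth$signatures[["emt_like"]]$genes
  emt_share1 <- sum(pb1$expr$values[genes, ]) / sum(pb1$expr$values)
  emt_share_fib <- sum(sc$expr$values[genes, fib_cells]) /
    sum(sc$expr$values[, fib_cells])
  expect_equal(emt_share1, emt_share_fib, tolerance = 0.05)

  # annotation must cover fibroblast and malignant cells
  ann_no_fib <- cell_annotation(sc$annotation$cell_id,
                                rep("malignant", nrow(sc$annotation)))
  expect_error(make_pseudobulk(sc$expr, ann_no_fib, des), "fibroblast")
})

test_that("EMT-like pseudobulk scores rise monotonically with fibroblast content", {
  sc <- generate_single_cell(sc_small(seed = 7))
  pb <- make_pseudobulk(sc$expr, sc$annotation,
                        pseudobulk_design(cells_per_sample = 500, seed = 8))
  tpm <- length_normalized_tpm(pb$expr)
  sc_emt <- score_bulk(tpm, sc$truth$signatures[["emt_like"]])
  rho <- cor(as.numeric(sc_emt), pb$fractions$fibroblast_fraction,
             method = "spearman")
  expect_gte(rho, 0.95)
})

test_that("bulk cohort mixtures track purity with planted signature truth", {
  bulk <- generate_bulk_cohort(bulk_cohort_config(n_samples = 60, n_nat = 10,
                                                  seed = 9))
  expect_identical(bulk$expr$values,
                   generate_bulk_cohort(bulk_cohort_config(n_samples = 60,
                                                           n_nat = 10,
                                                           seed = 9))$expr$values)
  expect_equal(sum(bulk$nat), 10)
  expect_true(all(bulk$purity$purity[bulk$nat[bulk$purity$sample_id]] == 0))
  expect_equal(nrow(bulk$pairing), 10)

  tpm <- length_normalized_tpm(bulk$expr)
  tumor <- names(bulk$nat)[!bulk$nat]
  scores <- score_bulk_collection(em_subset(tpm, columns = tumor),
                                  bulk$truth$signatures)
  pur <- bulk$purity$purity[match(tumor, bulk$purity$sample_id)]
  expect_lte(cor(scores$values["emt_like", ], pur), -0.9)
  expect_gte(cor(scores$values["proliferation_like", ], pur), 0.9)
})

test_that("subtype cohorts plant label-specific up-regulation deterministically", {
  cfg <- subtype_cohort_config(n_per_label = c(CMS1 = 20, CMS2 = 20,
                                               CMS3 = 20, CMS4 = 40),
                               seed = 10)
  a <- generate_subtype_cohort(cfg)
  b <- generate_subtype_cohort(cfg)
  expect_identical(a$expr$values, b$expr$values)
  planted <- a$truth$planted_genes$CMS4
  expect_length(planted, 10)
  in4 <- names(a$labels)[a$labels == "CMS4"]
  rest <- names(a$labels)[a$labels != "CMS4"]
  lfc <- log2(rowMeans(a$expr$values[planted, in4]) /
                rowMeans(a$expr$values[planted, rest]))
  expect_true(all(lfc > 2))   # planted log2 effect 3 clears the threshold

  expect_error(subtype_cohort_config(n_per_label = c(CMS1 = 0, CMS4 = 10)),
               "0 samples")
})
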