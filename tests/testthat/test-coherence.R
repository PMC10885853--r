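test_that("coherence score equals the mean of hand-computed pairwise Pearson", {
  # identical profiles: all pairs r = 1
  m <- matrix(rep(c(1, 2, 3, 4), 3), 3, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), sprintf("s%d", 1:4)))
  expect_equal(as.numeric(coherence_score(make_em(m, "tmm_tpm"),
                                          c("g1", "g2", "g3"))), 1)

  # g1 = (1,2,3,4), g2 = 2*g1, g3 reversed: CS = (1 - 1 - 1)/3
  m2 <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8), g3 = c(4, 3, 2, 1))
  colnames(m2) <- sprintf("s%d", 1:4)
  expect_equal(as.numeric(coherence_score(make_em(m2, "tmm_tpm"),
                                          c("g1", "g2", "g3"))),
               -1 / 3, tolerance = 1e-12)
})

test_that("coherence score matches brute force on random 5x20 fixtures", {
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(runif(20 * 20, 0, 50), 20, 20,
                dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:20)))
    genes <- sample(rownames(m), 5)
    expect_equal(as.numeric(coherence_score(make_em(m, "tmm_tpm"), genes)),
                 brute_cs(m, genes), tolerance = 1e-12)
  }
})

test_that("zero-variance genes are dropped; too few usable genes give NA", {
  m <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 1, 4, 3), g3 = c(5, 5, 5, 5),
             g4 = c(1, 3, 2, 4))
  colnames(m) <- sprintf("s%d", 1:4)
  em <- make_em(m, "tmm_tpm")
  expect_warning(cs <- coherence_score(em, c("g1", "g2", "g3", "g4")),
                 "zero-variance")
  expect_equal(attr(cs, "n_genes_used"), 3L)
  expect_warning(cs2 <- coherence_score(em, c("g1", "g2", "g3")), "zero-variance")
  expect_true(is.na(cs2))
  expect_equal(attr(cs2, "n_genes_used"), 2L)
})

test_that("CS is affine-invariant, bounded, and sample-permutation invariant", {
  set.seed(11)
  m <- matrix(rnorm(10 * 30, 50, 10), 10, 30,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:30)))
  genes <- c("g01", "g04", "g07", "g09")
  cs <- as.numeric(coherence_score(m, genes))
  expect_true(abs(cs) <= 1)

  m_aff <- m
  m_aff["g04", ] <- 3.7 * m_aff["g04", ] + 12     # positive affine transform
  expect_equal(as.numeric(coherence_score(m_aff, genes)), cs, tolerance = 1e-12)

  perm <- sample(ncol(m))
  m_perm <- m[, perm]
  colnames(m_perm) <- colnames(m)
  expect_equal(as.numeric(coherence_score(m_perm, genes)), cs,
               tolerance = 1e-12)
})

test_that("the permutation null is centered at zero and seeded", {
  set.seed(12)
  m <- matrix(rnorm(500 * 380), 500, 380,
              dimnames = list(sprintf("g%03d", 1:500), sprintf("s%03d", 1:380)))
  null <- coherence_null(m, set_size = 5, n_draws = 1000, seed = 21)
  expect_equal(mean(null), 0, tolerance = 0.01)
  expect_identical(null, coherence_null(m, set_size = 5, n_draws = 1000,
                                        seed = 21))
  # null CS values agree with direct computation for spot-checked draws
  expect_equal(null[1],
               withr::with_seed(21, {
                 idx <- sample.int(500, 5)
                 brute_cs(m, rownames(m)[idx])
               }), tolerance = 1e-12)
  expect_error(coherence_null(m, set_size = 501, n_draws = 10), "exceeds")
  expect_error(coherence_null(m, set_size = 5, n_draws = 0), "n_draws")

  ident <- matrix(rep(1:10, 5), 5, 10, byrow = TRUE,
                  dimnames = list(sprintf("g%d", 1:5), sprintf("s%02d", 1:10)))
  expect_equal(unique(coherence_null(ident, 3, n_draws = 20, seed = 1)), 1)
})

test_that("permutation P-values use the add-one upper-tail estimate", {
  null <- seq(0, 0.9, length.out = 999)
  expect_equal(coherence_pvalue(1.0, null), 1 / 1000)
  expect_equal(coherence_pvalue(-2, null), 1)
  expect_true(is.na(coherence_pvalue(NA_real_, null)))
  expect_error(coherence_pvalue(0.5, numeric(0)), "empty")
})

test_that("a CS of 0.18 for five genes is significant on cohort-sized data", {
  set.seed(13)
  m <- matrix(rnorm(2000 * 380), 2000, 380,
              dimnames = list(sprintf("g%04d", 1:2000), sprintf("s%03d", 1:380)))
  null <- coherence_null(m, set_size = 5, n_draws = 2000, seed = 31)
  expect_lt(coherence_pvalue(0.18, null), 0.01)
})

test_that("coherence filtering keeps defined CS strictly above threshold", {
  sigs <- signature_collection(list(gene_signature("a", "g1"),
                                    gene_signature("b", "g2"),
                                    gene_signature("c", "g3"),
                                    gene_signature("d", "g4")))
  rep <- data.frame(signature = c("a", "b", "c", "d"),
                    n_genes_used = c(5L, 5L, 5L, 1L),
                    cs = c(0.5, 0.18, 0.3, NA),
                    p_value = c(0.001, 0.2, 0.01, NA),
                    n_draws = c(1000L, 1000L, 1000L, 0L),
                    pass = c(TRUE, FALSE, TRUE, FALSE))
  class(rep) <- c("CoherenceReport", "data.frame")
  kept <- filter_coherent(rep, sigs, threshold = 0.18)
  expect_equal(names(kept), c("a", "c"))   # 0.18 exactly and NA are dropped
})

test_that("removing top-scoring samples worsens a subgroup-driven CS", {
  # a signature co-activated in a small sample subgroup: coherent overall,
  # much less coherent once the high-scoring samples are removed
  set.seed(14)
  n_genes <- 12; n_samp <- 60
  m <- matrix(rnorm(n_genes * n_samp, 100, 5), n_genes, n_samp,
              dimnames = list(sprintf("g%02d", 1:n_genes),
                              sprintf("s%02d", 1:n_samp)))
  active <- 1:6                       # subgroup with the program switched on
  m[, active] <- m[, active] + 40
  genes <- rownames(m)
  cs_all <- as.numeric(coherence_score(make_em(m, "tmm_tpm"), genes))
  scores <- colMeans(m)
  keep <- rank(-scores) > ceiling(0.1 * n_samp)   # drop the top decile
  cs_trim <- as.numeric(coherence_score(make_em(m[, keep], "tmm_tpm"), genes))
  expect_gt(cs_all, 0.5)
  expect_lt(cs_trim, cs_all - 0.2)
})
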