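make_scores <- function(m) score_matrix(m, scored_layer = "tmm_tpm")

test_that("score-purity correlation handles exact, constant, and sparse cases", {
  pur <- purity_table(sprintf("s%d", 1:6), seq(0.2, 0.95, length.out = 6))
  m <- rbind(mirror = seq(0.2, 0.95, length.out = 6),
             flat = rep(2, 6))
  colnames(m) <- sprintf("s%d", 1:6)
  out <- correlate_scores(make_scores(m), pur)
  expect_equal(out$r[out$signature == "mirror"], 1)
  expect_false(out$defined[out$signature == "flat"])
  expect_true(is.na(out$r[out$signature == "flat"]))
  expect_equal(out$n_overlap, c(6L, 6L))

  pur2 <- purity_table(c("s1", "s2"), c(0.5, 0.6))
  expect_error(correlate_scores(make_scores(m), pur2), "3 overlapping")

  # affine rescaling of scores (sign-preserving) leaves r unchanged
  m2 <- rbind(a = rnorm(6, 10, 3)); colnames(m2) <- sprintf("s%d", 1:6)
  r1 <- correlate_scores(make_scores(m2), pur)$r
  r2 <- correlate_scores(make_scores(2.5 * m2 + 7), pur)$r
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("family comparison reports rank-sum p and both effect sizes", {
  # strongly negative EMT family vs mildly positive rest
  set.seed(20)
  r_table <- data.frame(
    signature = sprintf("sig%02d", 1:33),
    r = c(rnorm(11, -0.9, 0.02), rnorm(22, 0.1, 0.05)),
    stringsAsFactors = FALSE)
  fam <- setNames(c(rep("EMT", 11), rep("process", 22)), r_table$signature)
  out <- summarize_family_correlations(r_table, fam, "EMT",
                                       alternative = "less")
  expect_lt(out$p_value, 1e-4)
  expect_equal(out$effect_size_rank_biserial, 1)  # complete separation
  expect_gt(out$effect_size, 0.5)
  expect_equal(out$n_target, 11)
  med <- out$family_medians
  expect_lt(med$median_r[med$family == "EMT"], -0.8)

  # all equal: mid-rank ties, effect size ~ 0, p in the 0.5 region
  r_eq <- data.frame(signature = r_table$signature, r = rep(0.3, 33))
  out_eq <- summarize_family_correlations(r_eq, fam, "EMT")
  expect_equal(out_eq$effect_size, 0, tolerance = 0.1)
  expect_equal(out_eq$effect_size_rank_biserial, 0)
  expect_gt(out_eq$p_value, 0.4)

  expect_error(summarize_family_correlations(r_table, fam, "unknown_family"),
               "target family")
})

test_that("purity quartile groups follow the at-or-beyond rule and NAT wins", {
  pur <- purity_table(sprintf("t%02d", 1:20), seq(0.05, 1, by = 0.05))
  grp <- purity_groups(pur)
  expect_equal(sum(grp == "T_low"), 5)
  expect_equal(sum(grp == "T_high"), 5)
  expect_equal(sum(grp == "T_mid"), 10)

  # ties at the cutoff land in the extreme group
  pur_tie <- purity_table(sprintf("t%02d", 1:8),
                          c(0.2, 0.2, 0.2, 0.5, 0.6, 0.9, 0.9, 0.9))
  grp_tie <- purity_groups(pur_tie)
  expect_equal(sum(grp_tie == "T_low"), 3)
  expect_equal(sum(grp_tie == "T_high"), 3)

  # a NAT-flagged sample is NAT regardless of recorded purity
  pur_nat <- purity_table(c(sprintf("t%d", 1:5), "n1"),
                          c(0.2, 0.4, 0.6, 0.8, 0.9, 0.9))
  grp_nat <- purity_groups(pur_nat, nat = "n1")
  expect_equal(unname(grp_nat["n1"]), "NAT")
  expect_error(purity_groups(purity_table("n1", 0.5), nat = "n1"), "NAT")
})

test_that("group comparisons run the stated one-sided tests with Bonferroni", {
  set.seed(21)
  ids <- c(sprintf("low%d", 1:20), sprintf("high%d", 1:20),
           sprintf("nat%d", 1:10))
  groups <- setNames(c(rep("T_low", 20), rep("T_high", 20), rep("NAT", 10)),
                     ids)
  pairing <- data.frame(tumor = sprintf("high%d", 1:10),
                        nat = sprintf("nat%d", 1:10))

  # identical distributions: ns
  m_null <- matrix(rnorm(length(ids)), 1, dimnames = list("flat", ids))
  out_null <- compare_groups(make_scores(m_null), groups, pairing)
  expect_true(all(out_null$stars == "ns"))
  expect_true(all(out_null$adj_p >= out_null$raw_p))

  # planted 3-pooled-SD shift in T_low and NAT: strong stars
  shift <- rnorm(length(ids))
  names(shift) <- ids
  shift[grepl("^low|^nat", ids)] <- shift[grepl("^low|^nat", ids)] + 3
  m_shift <- matrix(shift, 1, dimnames = list("shifted", ids))
  out_shift <- compare_groups(make_scores(m_shift), groups, pairing)
  expect_true(all(out_shift$stars %in% c("***", "****")))
  expect_equal(out_shift$test,
               c("t_one_sided", "t_paired_one_sided"))

  # Bonferroni family: 10 signatures x 2 comparisons = factor 20
  m10 <- matrix(rnorm(10 * length(ids)), 10,
                dimnames = list(sprintf("sig%02d", 1:10), ids))
  out10 <- compare_groups(make_scores(m10), groups, pairing)
  expect_equal(nrow(out10), 20)
  expect_equal(out10$adj_p, pmin(1, out10$raw_p * 20))

  # no complete pairs: paired comparison skipped with warning
  expect_warning(
    out_np <- compare_groups(make_scores(m_null), groups,
                             data.frame(tumor = "absent", nat = "nat1")),
    "skipped")
  expect_equal(out_np$comparison, "Thigh_vs_Tlow")
})

test_that("raw group-test p-values are calibrated under label permutation", {
  set.seed(22)
  n <- 40
  ids <- sprintf("s%02d", 1:n)
  scores <- make_scores(matrix(rnorm(n), 1, dimnames = list("null_sig", ids)))
  base_groups <- c(rep("T_low", 10), rep("T_mid", 20), rep("T_high", 10))
  raw_p <- replicate(500, {
    g <- setNames(sample(base_groups), ids)
    compare_groups(scores, g)$raw_p
  })
  frac <- mean(raw_p <= 0.10)
  expect_gte(frac, 0.05)
  expect_lte(frac, 0.15)
})
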