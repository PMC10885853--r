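# Score-purity association: per-signature Pearson correlations, purity
# quartile / NAT group construction, and the group hypothesis tests with
# Bonferroni correction and star coding.

#' Correlate signature scores with a per-sample covariate
#'
#' Pearson correlation of each signature's score vector with the covariate
#' (typically tumor purity) over the sample intersection. A constant score
#' vector yields an undefined correlation, flagged rather than thrown, so
#' whole collections can be screened.
#'
#' @param scores A [score_matrix()].
#' @param covariate A [purity_table()] (or any data frame with `sample_id`
#'   and a numeric second column).
#' @return Data frame: `signature`, `r`, `n_overlap`, `defined`.
#' @export
correlate_scores <- function(scores, covariate) {
  stopifnot(inherits(scores, "ScoreMatrix"))
  cov_vals <- stats::setNames(covariate[[2]], covariate[[1]])
  common <- intersect(colnames(scores$values), names(cov_vals))
  if (length(common) < 3) {
    stop("fewer than 3 overlapping samples between scores and covariate",
         call. = FALSE)
  }
  z <- cov_vals[common]
  if (stats::var(z) == 0) stop("covariate is constant on the overlap", call. = FALSE)
  out <- data.frame(signature = rownames(scores$values),
                    r = NA_real_, n_overlap = length(common),
                    defined = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(scores$values))) {
    s <- scores$values[i, common]
    if (stats::var(s) > 0) {
      out$r[i] <- stats::cor(s, z)
      out$defined[i] <- TRUE
    }
  }
  out
}

# Wilcoxon rank-sum machinery shared by the family comparison and the
# single-cell marker test: normal approximation with tie correction and
# continuity correction, matching stats::wilcox.test(exact = FALSE).
rank_sum_z <- function(x, y, correct = TRUE) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U of x
  nt <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(nt^3 - nt) / (n * (n - 1)))
  mu <- n1 * n2 / 2
  z <- W - mu
  cc <- if (correct) sign(z) * 0.5 else 0
  z_std <- if (sigma2 > 0) (z - cc) / sqrt(sigma2) else 0
  list(U = W, z = z_std, n1 = n1, n2 = n2)
}

#' Compare purity correlations of a signature family against the rest
#'
#' One-sided Wilcoxon rank-sum test asking whether a target family of
#' signatures (e.g. the EMT-related family) has systematically lower (or
#' higher, or larger in magnitude) purity correlations than the remaining
#' signatures, with per-family medians and two effect sizes: `effect_size`
#' is `|Z| / sqrt(N)` (the 0-to-1 scale used when reporting rank tests on
#' cohort data) and `effect_size_rank_biserial` is `1 - 2U/(n1*n2)` oriented
#' so that 1 means complete separation in the alternative's direction.
#'
#' @param r_table Data frame from [correlate_scores()].
#' @param families Named character vector: signature name to family label.
#' @param target_family Family to test against all other signatures.
#' @param value `"r"` (signed correlations) or `"abs_r"` (magnitudes).
#' @param alternative `"less"` (target family lower), `"greater"`, or
#'   `"two.sided"`.
#' @return A list with `family_medians` (data frame), `p_value`,
#'   `effect_size`, `effect_size_rank_biserial`, `n_target`, `n_rest`.
#' @export
summarize_family_correlations <- function(r_table, families, target_family,
                                          value = c("r", "abs_r"),
                                          alternative = c("less", "greater",
                                                          "two.sided")) {
  value <- match.arg(value)
  alternative <- match.arg(alternative)
  fam <- families[r_table$signature]
  if (!target_family %in% fam) {
    stop("unknown or empty target family: ", target_family, call. = FALSE)
  }
  vals <- if (value == "abs_r") abs(r_table$r) else r_table$r
  ok <- !is.na(vals) & !is.na(fam)
  vals <- vals[ok]; fam <- fam[ok]
  x <- vals[fam == target_family]
  y <- vals[fam != target_family]
  if (!length(y)) stop("comparison set is empty", call. = FALSE)
  medians <- stats::aggregate(list(median_r = vals), list(family = fam),
                              stats::median)
  p <- stats::wilcox.test(x, y, alternative = alternative,
                          exact = FALSE)$p.value
  rs <- rank_sum_z(x, y)
  rb <- 1 - 2 * rs$U / (rs$n1 * rs$n2)            # 1 when x entirely below y
  if (alternative == "greater") rb <- -rb
  list(family_medians = medians,
       p_value = p,
       effect_size = abs(rs$z) / sqrt(rs$n1 + rs$n2),
       effect_size_rank_biserial = rb,
       n_target = rs$n1, n_rest = rs$n2)
}

#' Assign samples to purity groups
#'
#' Tumor samples at or below the 25th percentile of tumor purity form
#' `T_low`, those at or above the 75th percentile form `T_high`, the rest
#' `T_mid`. NAT-flagged samples are assigned to `NAT` regardless of any
#' recorded purity.
#'
#' @param purity A [purity_table()] covering tumor and NAT samples.
#' @param nat Character vector of NAT sample IDs (or a named logical vector
#'   of NAT flags).
#' @return Named character vector: sample ID to group.
#' @export
purity_groups <- function(purity, nat = character()) {
  if (is.logical(nat)) nat <- names(nat)[nat]
  ids <- purity$sample_id
  tumor <- setdiff(ids, nat)
  if (!length(tumor)) stop("all samples are NAT; no tumor samples to group",
                           call. = FALSE)
  if (length(tumor) < 4) stop("need at least 4 tumor samples", call. = FALSE)
  p <- stats::setNames(purity$purity, ids)[tumor]
  q <- stats::quantile(p, c(0.25, 0.75))
  grp <- ifelse(p <= q[1], "T_low", ifelse(p >= q[2], "T_high", "T_mid"))
  out <- c(grp, stats::setNames(rep("NAT", length(intersect(nat, ids))),
                                intersect(nat, ids)))
  out[ids]
}

stars_from_p <- function(p) {
  ifelse(is.na(p), "ns",
         ifelse(p < 1e-15, "****",
                ifelse(p < 1e-4, "***",
                       ifelse(p < 1e-3, "**",
                              ifelse(p < 0.05, "*", "ns")))))
}

cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  if (sp == 0) return(0)
  (mean(x) - mean(y)) / sp
}

#' Group comparisons of signature scores across purity strata
#'
#' Per signature, two one-sided tests mirroring the purity-stratified
#' comparison design: a two-sample *t* test of `T_low > T_high` (scores are
#' expected to rise as cancer-cell content falls for stromally driven
#' signatures), and a paired *t* test of `NAT > T_high` over complete
#' tumor/NAT pairs. P-values are Bonferroni-adjusted over all tests in the
#' family (every signature x comparison actually performed) and mapped to
#' stars: `< 1e-15 = ****`, `< 1e-4 = ***`, `< 0.001 = **`, `< 0.05 = *`,
#' else `ns`.
#'
#' @param scores A [score_matrix()].
#' @param groups Named character vector from [purity_groups()].
#' @param pairing Optional data frame with columns `tumor`, `nat` giving
#'   paired sample IDs; required for the NAT comparison.
#' @return Data frame of class `GroupComparisonResult` with columns
#'   `signature`, `comparison`, `test`, `statistic`, `raw_p`, `adj_p`,
#'   `effect_size`, `stars`.
#' @export
compare_groups <- function(scores, groups, pairing = NULL) {
  stopifnot(inherits(scores, "ScoreMatrix"))
  ids <- colnames(scores$values)
  grp <- groups[ids]
  low_ids <- ids[!is.na(grp) & grp == "T_low"]
  high_ids <- ids[!is.na(grp) & grp == "T_high"]
  rows <- list()
  pairs_ok <- FALSE
  if (!is.null(pairing) && nrow(pairing)) {
    keep <- pairing$tumor %in% high_ids & pairing$nat %in% ids
    pairing <- pairing[keep, , drop = FALSE]
    pairs_ok <- nrow(pairing) >= 2
    if (!pairs_ok) {
      warning("no (or <2) complete tumor/NAT pairs in T_high; paired comparison skipped",
              call. = FALSE)
    }
  }
  for (sig in rownames(scores$values)) {
    s <- scores$values[sig, ]
    if (length(low_ids) >= 2 && length(high_ids) >= 2) {
      x <- s[low_ids]; y <- s[high_ids]
      tt <- stats::t.test(x, y, alternative = "greater")
      rows[[length(rows) + 1L]] <- data.frame(
        signature = sig, comparison = "Thigh_vs_Tlow", test = "t_one_sided",
        statistic = unname(tt$statistic), raw_p = tt$p.value,
        effect_size = cohens_d(x, y), stringsAsFactors = FALSE)
    }
    if (pairs_ok) {
      nat_v <- s[pairing$nat]; tum_v <- s[pairing$tumor]
      tt <- stats::t.test(nat_v, tum_v, paired = TRUE, alternative = "greater")
      d <- nat_v - tum_v
      rows[[length(rows) + 1L]] <- data.frame(
        signature = sig, comparison = "Thigh_vs_NAT", test = "t_paired_one_sided",
        statistic = unname(tt$statistic), raw_p = tt$p.value,
        effect_size = if (stats::sd(d) > 0) mean(d) / stats::sd(d) else 0,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no comparable groups (need >= 2 samples per group)",
                          call. = FALSE)
  out <- do.call(rbind, rows)
  out$adj_p <- pmin(1, out$raw_p * nrow(out))
  out$stars <- stars_from_p(out$adj_p)
  out <- out[, c("signature", "comparison", "test", "statistic", "raw_p",
                 "adj_p", "effect_size", "stars")]
  class(out) <- c("GroupComparisonResult", "data.frame")
  out
}
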