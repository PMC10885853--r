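# Single-cell attribution: which cell types carry a signature's signal.
# Marker testing between cell types, per-signature DEG percentages,
# per-cell-type dot statistics, and the gene-level triple association that
# links single-cell fold changes to bulk purity correlations.

#' Differential expression between two cell groups
#'
#' Per-gene two-sided Wilcoxon rank-sum test on log-normalized values
#' between `group1` and `group2` (or all remaining cells), with the
#' conventional single-cell fold change: the ratio of de-logged group means
#' with a pseudocount of one, reported as log2. A gene passes in a group's
#' direction when its fold change is at least `fc` that way *and* its
#' P-value is below `p`; the fold-change boundary is inclusive.
#'
#' The rank-sum P-value uses the tie-corrected normal approximation with
#' continuity correction (the large-sample path of `stats::wilcox.test`),
#' vectorized across genes.
#'
#' @param expr An [expression_matrix()] with `layer = "log_norm"`.
#' @param ann A [cell_annotation()] covering the cells.
#' @param group1 Cell type of interest (e.g. `"fibroblast"`).
#' @param group2 Second cell type, or `"rest"` for all other cells.
#' @param fc Fold-change threshold on the linear scale (default 2).
#' @param p P-value threshold (default 1e-10).
#' @return Data frame of class `DEResult`: `gene`, `log2fc`, `p_value`,
#'   `mean_group1`, `mean_group2`, `pct_group1`, `pct_group2`,
#'   `passed_in_group1`, `passed_in_group2`. Attributes `group1`, `group2`,
#'   `dataset_id`.
#' @export
find_markers <- function(expr, ann, group1, group2 = "rest", fc = 2,
                         p = 1e-10) {
  stopifnot(inherits(expr, "ExpressionMatrix"), inherits(ann, "CellAnnotation"))
  if (expr$layer != "log_norm") {
    stop("marker testing runs on the log_norm layer", call. = FALSE)
  }
  type_of <- stats::setNames(ann$cell_type, ann$cell_id)
  cells <- em_columns(expr)
  missing_ann <- cells[!cells %in% names(type_of)]
  if (length(missing_ann)) {
    stop("annotation does not cover all cells (e.g. ", missing_ann[1], ")",
         call. = FALSE)
  }
  ct <- type_of[cells]
  idx1 <- which(ct == group1)
  idx2 <- if (identical(group2, "rest")) which(ct != group1) else which(ct == group2)
  if (length(idx1) < 3 || length(idx2) < 3) {
    stop(sprintf("both groups need >= 3 cells (%s: %d, %s: %d)",
                 group1, length(idx1),
                 if (identical(group2, "rest")) "rest" else group2,
                 length(idx2)), call. = FALSE)
  }
  X <- expr$values
  n1 <- length(idx1); n2 <- length(idx2); n <- n1 + n2
  sub <- X[, c(idx1, idx2), drop = FALSE]
  # per-gene tie-corrected rank-sum normal approximation
  stat <- apply(sub, 1, function(v) {
    r <- rank(v)
    W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    nt <- table(v)
    tie_term <- sum(nt^3 - nt)
    c(W = W, tie = tie_term)
  })
  W <- stat["W", ]
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - stat["tie", ] / (n * (n - 1)))
  z <- W - n1 * n2 / 2
  z <- (z - sign(z) * 0.5) / sqrt(pmax(sigma2, .Machine$double.eps))
  pv <- 2 * stats::pnorm(-abs(z))
  pv <- pmin(pv, 1)
  pv[sigma2 <= 0] <- 1   # all-tied gene: no evidence
  delog1 <- rowMeans(2^X[, idx1, drop = FALSE] - 1)
  delog2 <- rowMeans(2^X[, idx2, drop = FALSE] - 1)
  log2fc <- log2((delog1 + 1) / (delog2 + 1))
  out <- data.frame(
    gene = rownames(X),
    log2fc = log2fc,
    p_value = pv,
    mean_group1 = rowMeans(X[, idx1, drop = FALSE]),
    mean_group2 = rowMeans(X[, idx2, drop = FALSE]),
    pct_group1 = rowMeans(X[, idx1, drop = FALSE] > 0),
    pct_group2 = rowMeans(X[, idx2, drop = FALSE] > 0),
    stringsAsFactors = FALSE, row.names = NULL)
  out$passed_in_group1 <- out$log2fc >= log2(fc) & out$p_value < p
  out$passed_in_group2 <- out$log2fc <= -log2(fc) & out$p_value < p
  attr(out, "group1") <- group1
  attr(out, "group2") <- if (identical(group2, "rest")) "rest" else group2
  attr(out, "dataset_id") <- attr(ann, "dataset_id")
  class(out) <- c("DEResult", "data.frame")
  out
}

#' Per-signature percentages of cell-type-dominant genes
#'
#' For each signature, the percentage of its genes (among those present in
#' the dataset(s)) that are differentially up-regulated in fibroblasts
#' (group 1 of the DE results) and in malignant cells (group 2). Multiple
#' datasets are pooled by union: a gene counts as available if present in
#' any dataset and as passed if it passed in any dataset.
#'
#' @param de A `DEResult` from [find_markers()] (fibroblast vs malignant),
#'   or a list of them from several datasets.
#' @param coll A [signature_collection()].
#' @return Data frame of class `AttributionReport`: `signature`,
#'   `pct_group1`, `pct_group2`, `n_available`, `defined`.
#' @export
signature_deg_fractions <- function(de, coll) {
  stopifnot(inherits(coll, "SignatureCollection"))
  if (inherits(de, "DEResult")) de <- list(de)
  ok <- vapply(de, inherits, logical(1), "DEResult")
  if (!all(ok)) stop("`de` must be DEResult objects", call. = FALSE)
  available <- Reduce(union, lapply(de, `[[`, "gene"))
  passed1 <- Reduce(union, lapply(de, function(d) d$gene[d$passed_in_group1]))
  passed2 <- Reduce(union, lapply(de, function(d) d$gene[d$passed_in_group2]))
  out <- data.frame(signature = names(coll),
                    pct_group1 = NA_real_, pct_group2 = NA_real_,
                    n_available = 0L, defined = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(coll)) {
    genes <- intersect(coll[[i]]$genes, available)
    out$n_available[i] <- length(genes)
    if (length(genes)) {
      out$pct_group1[i] <- 100 * length(intersect(genes, passed1)) / length(genes)
      out$pct_group2[i] <- 100 * length(intersect(genes, passed2)) / length(genes)
      out$defined[i] <- TRUE
    }
  }
  attr(out, "group1") <- attr(de[[1]], "group1")
  attr(out, "group2") <- attr(de[[1]], "group2")
  class(out) <- c("AttributionReport", "data.frame")
  out
}

#' Per-cell-type summary of module scores
#'
#' For each cell type in the annotation vocabulary: the mean module score
#' and the fraction of cells with a strictly positive score (the "cells
#' expressing the signature" convention of dot plots). Cell types without
#' any cells are flagged unavailable.
#'
#' @param scores Named numeric vector of per-cell module scores.
#' @param ann A [cell_annotation()] covering the scored cells.
#' @return Data frame: `cell_type`, `mean_score`, `fraction_positive`,
#'   `n_cells`, `available`.
#' @export
celltype_dot_stats <- function(scores, ann) {
  stopifnot(inherits(ann, "CellAnnotation"))
  type_of <- stats::setNames(ann$cell_type, ann$cell_id)
  cells <- names(scores)
  missing_ann <- cells[!cells %in% names(type_of)]
  if (length(missing_ann)) {
    stop("annotation does not cover all scored cells (e.g. ", missing_ann[1],
         ")", call. = FALSE)
  }
  ct <- type_of[cells]
  vocab <- attr(ann, "vocabulary")
  out <- data.frame(cell_type = vocab, mean_score = NA_real_,
                    fraction_positive = NA_real_, n_cells = 0L,
                    available = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(vocab)) {
    s <- scores[ct == vocab[i]]
    out$n_cells[i] <- length(s)
    if (length(s)) {
      out$mean_score[i] <- mean(s)
      out$fraction_positive[i] <- mean(s > 0)
      out$available[i] <- TRUE
    }
  }
  out
}

#' Gene-level triple association for one signature
#'
#' Links the three views of each signature gene: (i) its single-cell fold
#' change between fibroblasts and malignant cells, (ii) the Pearson
#' correlation of its bulk expression profile with tumor purity, and (iii)
#' the correlation of its bulk profile with the signature's own score
#' vector. Genes driving the bulk score from fibroblast expression show up
#' as high score correlation, negative purity correlation, and a fibroblast
#' DE flag.
#'
#' @param bulk An [expression_matrix()] of the bulk cohort (tmm_tpm layer).
#' @param purity A [purity_table()].
#' @param scores A [score_matrix()] containing the signature's row.
#' @param sig The [gene_signature()] to dissect.
#' @param sc_de A `DEResult` from [find_markers()] with fibroblasts as
#'   group 1 and malignant cells as group 2.
#' @return Data frame: `gene`, `r_gene_vs_score`, `r_gene_vs_purity`,
#'   `sc_log2fc`, `fibroblast_dominant`.
#' @export
gene_triple_table <- function(bulk, purity, scores, sig, sc_de) {
  stopifnot(inherits(bulk, "ExpressionMatrix"), inherits(scores, "ScoreMatrix"),
            inherits(sig, "GeneSignature"), inherits(sc_de, "DEResult"))
  if (!sig$name %in% rownames(scores$values)) {
    stop("signature '", sig$name, "' not present in the score matrix",
         call. = FALSE)
  }
  common <- intersect(colnames(scores$values), em_columns(bulk))
  common <- intersect(common, purity$sample_id)
  if (length(common) < 3) stop("fewer than 3 overlapping samples", call. = FALSE)
  present <- intersect(sig$genes, em_genes(bulk))
  absent <- setdiff(sig$genes, present)
  if (length(absent)) {
    warning(sprintf("signature '%s': %d gene(s) absent from bulk matrix, excluded",
                    sig$name, length(absent)), call. = FALSE)
  }
  if (!length(present)) stop("no signature gene present in bulk matrix", call. = FALSE)
  score_vec <- scores$values[sig$name, common]
  pur <- stats::setNames(purity$purity, purity$sample_id)[common]
  de_fc <- stats::setNames(sc_de$log2fc, sc_de$gene)
  de_pass <- stats::setNames(sc_de$passed_in_group1, sc_de$gene)
  out <- data.frame(gene = present,
                    r_gene_vs_score = NA_real_,
                    r_gene_vs_purity = NA_real_,
                    sc_log2fc = unname(de_fc[present]),
                    fibroblast_dominant = unname(de_pass[present]),
                    stringsAsFactors = FALSE)
  out$fibroblast_dominant[is.na(out$fibroblast_dominant)] <- FALSE
  for (i in seq_along(present)) {
    g <- bulk$values[present[i], common]
    if (stats::var(g) > 0) {
      if (stats::var(score_vec) > 0) out$r_gene_vs_score[i] <- stats::cor(g, score_vec)
      if (stats::var(pur) > 0) out$r_gene_vs_purity[i] <- stats::cor(g, pur)
    }
  }
  out
}
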