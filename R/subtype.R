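#' Derive a proxy gene set for a classifier-defined subtype
#'
#' Given a candidate gene list (e.g. genes extracted from a trained subtype
#' classifier) and a labeled expression cohort, keeps the candidates that
#' are significantly up-regulated in the target label versus all other
#' labels: a one-sided Welch *t* test (target greater) on `log2(x + 1)`
#' values, with the log2 fold change taken as the difference of log2-scale
#' group means, Benjamini-Hochberg adjustment over the tested candidates,
#' and the joint filter `log2FC > log2fc` (strict) and adjusted `P < adj_p`.
#'
#' @param candidates Character vector of candidate gene symbols.
#' @param cohort An [expression_matrix()] of the labeled cohort (any linear
#'   layer; values are log2(x+1)-transformed internally).
#' @param labels Named character vector: sample ID to subtype label.
#' @param target_label The label whose up-regulated genes are sought.
#' @param log2fc Log2 fold-change threshold (default 2, strict).
#' @param adj_p Adjusted P-value threshold (default 0.05).
#' @param name Name of the returned signature.
#' @return A list of class `SubtypeDerivation`: `genes` (the retained
#'   genes, possibly empty), `stats` (the per-candidate test table),
#'   `n_tested`, `thresholds`, and `signature` (a [gene_signature()] of the
#'   retained genes, or `NULL` when the derivation is empty, since a
#'   signature must contain at least one gene).
#' @export
derive_subtype_signature <- function(candidates, cohort, labels, target_label,
                                     log2fc = 2, adj_p = 0.05,
                                     name = paste0(target_label, "_proxy")) {
  stopifnot(inherits(cohort, "ExpressionMatrix"))
  candidates <- unique(as.character(candidates))
  if (!length(candidates)) stop("candidate list is empty", call. = FALSE)
  samples <- intersect(em_columns(cohort), names(labels))
  if (!length(samples)) stop("no labeled samples in cohort", call. = FALSE)
  lab <- labels[samples]
  if (!target_label %in% lab) {
    stop("target label '", target_label, "' absent from cohort", call. = FALSE)
  }
  in_target <- lab == target_label
  if (sum(in_target) < 3 || sum(!in_target) < 3) {
    stop("need >= 3 samples in the target label and >= 3 in the rest",
         call. = FALSE)
  }
  present <- intersect(candidates, em_genes(cohort))
  if (!length(present)) {
    stop("candidate list shares no genes with the cohort", call. = FALSE)
  }
  X <- log2(cohort$values[present, samples, drop = FALSE] + 1)
  x_t <- X[, in_target, drop = FALSE]
  x_r <- X[, !in_target, drop = FALSE]
  lfc <- rowMeans(x_t) - rowMeans(x_r)
  pv <- vapply(seq_along(present), function(i) {
    a <- x_t[i, ]; b <- x_r[i, ]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) return(1)
    stats::t.test(a, b, alternative = "greater", var.equal = FALSE)$p.value
  }, numeric(1))
  padj <- stats::p.adjust(pv, method = "BH")
  keep <- lfc > log2fc & padj < adj_p
  tab <- data.frame(gene = present, log2fc = lfc, p_value = pv,
                    adj_p = padj, kept = keep, stringsAsFactors = FALSE,
                    row.names = NULL)
  result <- list(genes = present[keep], stats = tab,
                 n_tested = length(present),
                 thresholds = c(log2fc = log2fc, adj_p = adj_p))
  if (any(keep)) {
    sig <- gene_signature(name, present[keep], category = "process",
                          source = sprintf(
                            "derived: %d/%d candidates, log2FC > %g, BH P < %g",
                            sum(keep), length(present), log2fc, adj_p))
    result$signature <- sig
  } else {
    result$signature <- NULL
  }
  class(result) <- "SubtypeDerivation"
  result
}

#' @export
print.SubtypeDerivation <- function(x, ...) {
  cat(sprintf("SubtypeDerivation: %d of %d tested candidates kept (log2FC > %g, BH P < %g)\n",
              length(x$genes), x$n_tested, x$thresholds["log2fc"],
              x$thresholds["adj_p"]))
  invisible(x)
}
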