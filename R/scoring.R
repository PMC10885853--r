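#' Configuration for single-cell module scoring
#'
#' @param n_bins Number of equal-frequency expression bins the gene universe
#'   is cut into (default 24).
#' @param n_ctrl Number of control genes drawn per signature gene
#'   (default 100).
#' @param seed Integer seed making the control draws reproducible.
#' @return A list of class `ModuleScoreConfig`.
#' @export
module_score_config <- function(n_bins = 24, n_ctrl = 100, seed = 1L) {
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  if (n_ctrl < 1) stop("n_ctrl must be >= 1", call. = FALSE)
  structure(list(n_bins = as.integer(n_bins), n_ctrl = as.integer(n_ctrl),
                 seed = as.integer(seed)),
            class = "ModuleScoreConfig")
}

#' Score a signature on bulk samples
#'
#' The bulk score of a signature in a sample is the arithmetic mean of the
#' sample's expression values over the signature genes present in the matrix
#' (mean TPM on TMM-normalized libraries in the default pipeline). With
#' `use_log = TRUE` the mean is taken over `log2(value + 1)` instead.
#'
#' @param expr An [expression_matrix()], conventionally the `tmm_tpm` layer.
#' @param sig A [gene_signature()].
#' @param use_log Average on the log2 scale instead of the linear scale.
#' @param min_genes Minimum number of signature genes that must be present.
#' @return Named numeric vector of per-sample scores, with attributes
#'   `genes_used` (character) and `n_genes_used`.
#' @export
score_bulk <- function(expr, sig, use_log = FALSE, min_genes = 3) {
  stopifnot(inherits(expr, "ExpressionMatrix"), inherits(sig, "GeneSignature"))
  present <- intersect(sig$genes, em_genes(expr))
  if (length(present) < min_genes) {
    missing <- setdiff(sig$genes, em_genes(expr))
    stop(sprintf(
      "signature '%s': only %d of %d genes present (min_genes = %d); missing: %s",
      sig$name, length(present), length(sig$genes), min_genes,
      paste(utils::head(missing, 10), collapse = ", ")), call. = FALSE)
  }
  sub <- expr$values[present, , drop = FALSE]
  if (use_log) sub <- log2(sub + 1)
  scores <- colMeans(sub)
  attr(scores, "genes_used") <- present
  attr(scores, "n_genes_used") <- length(present)
  scores
}

#' Score a collection of signatures on bulk samples
#'
#' Convenience wrapper building a [score_matrix()]; signatures with fewer
#' than `min_genes` genes present are dropped with a warning instead of
#' aborting the whole collection.
#'
#' @inheritParams score_bulk
#' @param coll A [signature_collection()].
#' @return A [score_matrix()] with one row per scorable signature.
#' @export
score_bulk_collection <- function(expr, coll, use_log = FALSE, min_genes = 3) {
  stopifnot(inherits(coll, "SignatureCollection"))
  rows <- list()
  for (s in coll) {
    sc <- tryCatch(score_bulk(expr, s, use_log = use_log, min_genes = min_genes),
                   error = function(e) {
                     warning(sprintf("skipping '%s': %s", s$name,
                                     conditionMessage(e)), call. = FALSE)
                     NULL
                   })
    if (!is.null(sc)) rows[[s$name]] <- as.numeric(sc)
  }
  m <- do.call(rbind, rows)
  if (is.null(m)) m <- matrix(0, 0, ncol(expr$values),
                              dimnames = list(NULL, em_columns(expr)))
  colnames(m) <- em_columns(expr)
  score_matrix(m, scored_layer = if (use_log) "log_norm" else expr$layer)
}

#' Control-adjusted module score for single cells
#'
#' Per-cell signature score following the standard single-cell module-score
#' convention: genes are ranked by their mean expression across cells and cut
#' into `n_bins` equal-frequency bins; every signature gene contributes
#' `n_ctrl` control genes drawn uniformly with replacement from its own bin;
#' a cell's score is the mean expression of the signature genes minus the
#' mean expression of the pooled control draws. Expression-tie bin assignment
#' is broken by stable gene order, and the control draws are seeded, so the
#' result is fully deterministic for a given configuration.
#'
#' @param expr An [expression_matrix()] with `layer = "log_norm"`.
#' @param sig A [gene_signature()]; at least one gene must be present.
#' @param cfg A [module_score_config()].
#' @return Named numeric vector of per-cell scores with attribute
#'   `genes_used`.
#' @export
score_single_cell <- function(expr, sig, cfg = module_score_config()) {
  stopifnot(inherits(expr, "ExpressionMatrix"), inherits(sig, "GeneSignature"),
            inherits(cfg, "ModuleScoreConfig"))
  if (expr$layer != "log_norm") {
    stop("module scores are computed on the log_norm layer", call. = FALSE)
  }
  X <- expr$values
  n_genes <- nrow(X)
  if (n_genes < cfg$n_bins) {
    stop(sprintf("need at least n_bins = %d genes, have %d", cfg$n_bins, n_genes),
         call. = FALSE)
  }
  present <- intersect(sig$genes, rownames(X))
  if (!length(present)) {
    stop(sprintf("signature '%s': no gene present in the matrix", sig$name),
         call. = FALSE)
  }
  gene_means <- rowMeans(X)
  rk <- rank(gene_means, ties.method = "first")
  bin <- ceiling(rk * cfg$n_bins / n_genes)
  names(bin) <- rownames(X)
  ctrl <- withr::with_seed(cfg$seed, {
    unlist(lapply(present, function(g) {
      pool <- rownames(X)[bin == bin[[g]]]
      pool[sample.int(length(pool), cfg$n_ctrl, replace = TRUE)]
    }), use.names = FALSE)
  })
  sig_mean <- colMeans(X[present, , drop = FALSE])
  ctrl_mean <- colMeans(X[ctrl, , drop = FALSE])  # draw multiplicity preserved
  scores <- sig_mean - ctrl_mean
  attr(scores, "genes_used") <- present
  scores
}

#' Jaccard index of two gene sets
#'
#' @param a,b Non-empty character vectors of gene symbols.
#' @return `|a n b| / |a u b|`, in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  if (!length(a) || !length(b)) stop("gene sets must be non-empty", call. = FALSE)
  length(intersect(a, b)) / length(union(a, b))
}

#' Remove redundant signatures by Jaccard overlap
#'
#' Greedy pass in collection order: a signature is dropped when its Jaccard
#' index with any *retained* earlier signature exceeds `threshold`.
#' Signatures named in `protected` are never dropped. Order is preserved, and
#' the operation is idempotent.
#'
#' @param coll A [signature_collection()].
#' @param threshold Jaccard index above which a signature counts as
#'   redundant (default 0.25).
#' @param protected Character vector of signature names exempt from dropping.
#' @return The filtered [signature_collection()].
#' @export
filter_redundant <- function(coll, threshold = 0.25, protected = character()) {
  stopifnot(inherits(coll, "SignatureCollection"))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]", call. = FALSE)
  unknown <- setdiff(protected, names(coll))
  if (length(unknown)) {
    stop("unknown protected signature name(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  kept <- list()
  for (s in coll) {
    redundant <- FALSE
    if (!(s$name %in% protected)) {
      for (k in kept) {
        if (jaccard_index(s$genes, k$genes) > threshold) {
          redundant <- TRUE
          break
        }
      }
    }
    if (!redundant) kept[[s$name]] <- s
  }
  signature_collection(unname(kept))
}
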