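#' Coherence score of a gene signature in a dataset
#'
#' The coherence score (CS) is the mean Pearson correlation over all
#' unordered pairs of a signature's gene expression profiles in a given
#' dataset. A CS near +1 indicates that the signature behaves as one
#' coordinated module there; a CS near 0 indicates no linear relationship
#' among its genes, i.e. the signature's per-sample scores cannot be
#' interpreted as the activity of a single program in that dataset.
#'
#' Genes with zero variance across samples are dropped (with a warning)
#' before computing correlations. If fewer than `min_genes` usable genes
#' remain, the CS is *undefined* and returned as `NA` rather than as an
#' error, so that large collections can be screened in bulk.
#'
#' @param expr An [expression_matrix()] (any layer; the pipeline default is
#'   the layer also used for scoring), or a plain numeric genes-by-samples
#'   matrix with rownames — correlations are location/scale invariant, so
#'   the CS is defined for arbitrary real profiles.
#' @param sig A [gene_signature()], or a plain character vector of genes.
#' @param min_genes Minimum number of usable genes (default 3).
#' @return A single numeric: the CS, or `NA` if undefined. Attribute
#'   `n_genes_used` records the number of genes that entered the mean.
#' @export
coherence_score <- function(expr, sig, min_genes = 3) {
  genes <- if (inherits(sig, "GeneSignature")) sig$genes else as.character(sig)
  X <- expr_values(expr)
  if (ncol(X) < 3) stop("coherence requires at least 3 samples", call. = FALSE)
  present <- intersect(genes, rownames(X))
  sub <- X[present, , drop = FALSE]
  if (nrow(sub)) {
    v <- apply(sub, 1, stats::var)
    n_zero <- sum(!(v > 0 & is.finite(v)))
    if (n_zero > 0) {
      warning(sprintf("dropping %d zero-variance gene(s) from CS computation",
                      n_zero), call. = FALSE)
      sub <- sub[v > 0 & is.finite(v), , drop = FALSE]
    }
  }
  n_used <- nrow(sub)
  if (n_used < min_genes) {
    out <- NA_real_
    attr(out, "n_genes_used") <- n_used
    return(out)
  }
  C <- stats::cor(t(sub))
  cs <- mean(C[upper.tri(C)])
  attr(cs, "n_genes_used") <- n_used
  cs
}

#' Permutation null distribution of the coherence score
#'
#' Draws `n_draws` random gene sets of exactly `set_size` genes, uniformly
#' without replacement from the genes with non-zero variance in `expr`, and
#' computes the CS of each. Because the sets are drawn from the same dataset,
#' the null preserves the dataset's background gene-gene correlation
#' structure.
#'
#' @param expr An [expression_matrix()] or a plain numeric genes-by-samples
#'   matrix with rownames.
#' @param set_size Number of genes per null set.
#' @param n_draws Number of null sets (default 10000).
#' @param seed Integer seed.
#' @return Numeric vector of `n_draws` null CS values.
#' @export
coherence_null <- function(expr, set_size, n_draws = 10000, seed = 1L) {
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  if (set_size < 2) stop("set_size must be >= 2", call. = FALSE)
  X <- expr_values(expr)
  if (ncol(X) < 3) stop("coherence requires at least 3 samples", call. = FALSE)
  v <- apply(X, 1, stats::var)
  elig <- which(v > 0 & is.finite(v))
  if (length(elig) < set_size) {
    stop(sprintf("set_size = %d exceeds the %d genes with non-zero variance",
                 set_size, length(elig)), call. = FALSE)
  }
  # Pearson r of two profiles is the dot product of their unit-norm centered
  # versions; standardizing once makes each draw a small crossproduct.
  Z <- X[elig, , drop = FALSE]
  Z <- Z - rowMeans(Z)
  Z <- Z / sqrt(rowSums(Z * Z))
  ut <- upper.tri(matrix(0, set_size, set_size))
  withr::with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      idx <- sample.int(nrow(Z), set_size)
      S <- tcrossprod(Z[idx, , drop = FALSE])
      mean(S[ut])
    }, numeric(1))
  })
}

#' Permutation P-value for an observed coherence score
#'
#' Upper-tail add-one estimate:
#' `P = (1 + #\{null >= observed\}) / (1 + n_draws)`.
#'
#' @param observed_cs Observed CS (may be `NA`, giving `NA`).
#' @param null_sample Numeric vector from [coherence_null()].
#' @return P-value in `(0, 1]`, or `NA` for an undefined CS.
#' @export
coherence_pvalue <- function(observed_cs, null_sample) {
  if (!length(null_sample)) stop("null sample is empty", call. = FALSE)
  if (is.na(observed_cs)) return(NA_real_)
  (1 + sum(null_sample >= observed_cs)) / (1 + length(null_sample))
}

#' Coherence report for a signature collection
#'
#' Computes the CS of every signature in `coll` on `expr`, with permutation
#' P-values from size-matched random gene sets (one null sample is computed
#' per distinct used-gene count and shared across signatures of that size).
#'
#' @param expr An [expression_matrix()].
#' @param coll A [signature_collection()].
#' @param min_genes Minimum usable genes per signature (default 3).
#' @param threshold CS pass threshold (default 0.18).
#' @param n_draws Null draws per set size (default 1000).
#' @param seed Integer seed for the null draws.
#' @return A data frame of class `CoherenceReport` with columns `signature`,
#'   `n_genes_used`, `cs`, `p_value`, `n_draws`, `pass`.
#' @export
coherence_report <- function(expr, coll, min_genes = 3, threshold = 0.18,
                             n_draws = 1000, seed = 1L) {
  stopifnot(inherits(coll, "SignatureCollection"))
  cs_vals <- numeric(length(coll))
  n_used <- integer(length(coll))
  for (i in seq_along(coll)) {
    cs <- coherence_score(expr, coll[[i]], min_genes = min_genes)
    cs_vals[i] <- as.numeric(cs)
    n_used[i] <- attr(cs, "n_genes_used")
  }
  null_cache <- list()
  p_vals <- rep(NA_real_, length(coll))
  for (i in seq_along(coll)) {
    if (is.na(cs_vals[i])) next
    key <- as.character(n_used[i])
    if (is.null(null_cache[[key]])) {
      null_cache[[key]] <- coherence_null(expr, set_size = n_used[i],
                                          n_draws = n_draws, seed = seed)
    }
    p_vals[i] <- coherence_pvalue(cs_vals[i], null_cache[[key]])
  }
  out <- data.frame(signature = names(coll), n_genes_used = n_used,
                    cs = cs_vals, p_value = p_vals,
                    n_draws = ifelse(is.na(cs_vals), 0L, as.integer(n_draws)),
                    pass = !is.na(cs_vals) & cs_vals > threshold,
                    stringsAsFactors = FALSE)
  attr(out, "cs_threshold") <- threshold
  class(out) <- c("CoherenceReport", "data.frame")
  out
}

#' Keep the coherently expressed (translatable) signatures
#'
#' Filters a collection to the signatures whose CS on the screening dataset
#' is defined and strictly greater than `threshold` (default 0.18, the
#' operating point at which even five-gene signatures reach permutation
#' P < 0.01 on cohort-sized data).
#'
#' @param reports A `CoherenceReport` from [coherence_report()].
#' @param coll The [signature_collection()] the report was computed on.
#' @param threshold CS threshold (strict inequality; default 0.18).
#' @return The subset [signature_collection()], order preserved.
#' @export
filter_coherent <- function(reports, coll, threshold = 0.18) {
  stopifnot(inherits(reports, "CoherenceReport"),
            inherits(coll, "SignatureCollection"))
  keep <- reports$signature[!is.na(reports$cs) & reports$cs > threshold]
  keep <- keep[keep %in% names(coll)]
  if (!length(keep)) {
    return(signature_collection(list()))
  }
  coll[keep]
}
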