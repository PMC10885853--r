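# Accept either an ExpressionMatrix or a bare genes-by-samples numeric
# matrix with rownames (used by the correlation-based operations, which are
# defined for arbitrary real profiles).
expr_values <- function(expr) {
  if (inherits(expr, "ExpressionMatrix")) return(expr$values)
  if (is.matrix(expr) && is.numeric(expr) && !is.null(rownames(expr))) {
    return(expr)
  }
  stop("expected an ExpressionMatrix or a numeric matrix with rownames",
       call. = FALSE)
}

#' Construct an expression matrix
#'
#' The central container of the package: a dense genes-by-columns matrix of
#' expression values carrying a layer tag that records what the values mean.
#' Columns are bulk samples or single cells. The three layers are:
#'
#' * `counts` — raw (integer-valued) read or UMI counts,
#' * `tmm_tpm` — gene-length-normalized TPM on TMM-scaled libraries,
#' * `log_norm` — `log2(x + 1)` of a depth-normalized layer.
#'
#' Missing values are never permitted: downstream Pearson correlations and
#' means are undefined on `NA`, so an `NA` anywhere is a hard error rather
#' than a silent propagation.
#'
#' @param values Numeric matrix with unique, non-empty rownames (gene IDs)
#'   and colnames (sample or cell IDs).
#' @param layer One of `"counts"`, `"tmm_tpm"`, `"log_norm"`.
#' @param gene_lengths Optional positive numeric vector of gene lengths in
#'   bases, either named by gene ID or in row order of `values`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `layer`, `gene_lengths`.
#' @export
expression_matrix <- function(values,
                              layer = c("counts", "tmm_tpm", "log_norm"),
                              gene_lengths = NULL) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have rownames (gene IDs) and colnames (column IDs)",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene IDs are not permitted", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate column IDs are not permitted", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("missing values are not permitted in expression layers", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("non-finite expression values are not permitted", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("negative expression values are not permitted", call. = FALSE)
  }
  if (layer == "counts" && any(abs(values - round(values)) > 1e-6)) {
    stop("counts layer must be integer-valued", call. = FALSE)
  }
  if (!is.null(gene_lengths)) {
    if (!is.null(names(gene_lengths))) {
      missing <- setdiff(rownames(values), names(gene_lengths))
      if (length(missing)) {
        stop("gene_lengths missing for: ", paste(utils::head(missing, 5),
             collapse = ", "), call. = FALSE)
      }
      gene_lengths <- gene_lengths[rownames(values)]
    } else if (length(gene_lengths) != nrow(values)) {
      stop("unnamed gene_lengths must match the number of genes", call. = FALSE)
    } else {
      names(gene_lengths) <- rownames(values)
    }
    if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0)) {
      stop("gene_lengths must be finite and positive", call. = FALSE)
    }
  }
  structure(list(values = values, layer = layer, gene_lengths = gene_lengths),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d columns [layer: %s%s]\n",
              nrow(x$values), ncol(x$values), x$layer,
              if (is.null(x$gene_lengths)) "" else ", with gene lengths"))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene identifiers of an expression matrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of gene IDs.
#' @export
em_genes <- function(x) rownames(x$values)

#' Column (sample or cell) identifiers of an expression matrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of column IDs.
#' @export
em_columns <- function(x) colnames(x$values)

#' Subset an expression matrix by genes and/or columns
#'
#' @param x An `ExpressionMatrix`.
#' @param genes,columns Character vectors of IDs to keep (default: all).
#' @return An `ExpressionMatrix` restricted to the requested rows/columns.
#' @export
em_subset <- function(x, genes = NULL, columns = NULL) {
  v <- x$values
  gl <- x$gene_lengths
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing)) {
      stop("unknown gene IDs: ", paste(utils::head(missing, 5), collapse = ", "),
           call. = FALSE)
    }
    v <- v[genes, , drop = FALSE]
    if (!is.null(gl)) gl <- gl[genes]
  }
  if (!is.null(columns)) {
    missing <- setdiff(columns, colnames(v))
    if (length(missing)) {
      stop("unknown column IDs: ", paste(utils::head(missing, 5), collapse = ", "),
           call. = FALSE)
    }
    v <- v[, columns, drop = FALSE]
  }
  expression_matrix(v, layer = x$layer, gene_lengths = gl)
}
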