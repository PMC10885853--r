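#' Trimmed-mean-of-M-values scaling factors
#'
#' Between-sample scaling factors for count libraries, computed with the TMM
#' method as implemented in edgeR: the reference library is the one whose
#' 75th-percentile-to-library-size ratio is closest to the mean of those
#' ratios; per sample, log2 ratios (M) and average log2 abundances (A)
#' against the reference are computed over genes non-zero in both, doubly
#' trimmed (`trim_m` on M, `trim_a` on A), and the factor is two to the
#' precision-weighted mean of the retained M values. Factors are rescaled so
#' their geometric mean is one.
#'
#' @param counts An [expression_matrix()] with `layer = "counts"`.
#' @param trim_m Fraction trimmed from each tail of the M values (default 0.3).
#' @param trim_a Fraction trimmed from each tail of the A values (default 0.05).
#' @param a_cutoff Minimum A value retained (default effectively none).
#' @return An object of class `TmmFactors`: named numeric `factors` with
#'   geometric mean 1, plus `reference_sample` and `lib_size`.
#' @export
tmm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05, a_cutoff = -1e10) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$layer != "counts") {
    stop("TMM factors are defined on the counts layer", call. = FALSE)
  }
  x <- counts$values
  if (ncol(x) < 2L) stop("TMM requires at least 2 samples", call. = FALSE)
  lib <- colSums(x)
  if (any(lib <= 0)) {
    stop("samples with zero library size: ",
         paste(colnames(x)[lib <= 0], collapse = ", "), call. = FALSE)
  }
  # reference library per the TMM rule (75th-percentile ratio closest to mean)
  f75 <- apply(x, 2, function(col) stats::quantile(col, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  shared <- vapply(seq_len(ncol(x)),
                   function(j) any(x[, j] > 0 & x[, ref] > 0), logical(1))
  if (!all(shared)) {
    stop("sample(s) share no non-zero genes with the reference: ",
         paste(colnames(x)[!shared], collapse = ", "), call. = FALSE)
  }
  f <- edgeR::calcNormFactors(x, lib.size = lib, method = "TMM",
                              refColumn = ref, logratioTrim = trim_m,
                              sumTrim = trim_a, doWeighting = TRUE,
                              Acutoff = a_cutoff)
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("TMM produced non-finite scaling factors", call. = FALSE)
  }
  f <- f / exp(mean(log(f)))  # enforce geometric mean 1 exactly
  names(f) <- colnames(x)
  structure(list(factors = f, reference_sample = colnames(x)[ref],
                 lib_size = lib),
            class = "TmmFactors")
}

#' @export
print.TmmFactors <- function(x, ...) {
  cat(sprintf("TmmFactors for %d samples (reference: %s)\n",
              length(x$factors), x$reference_sample))
  print(round(x$factors, 4))
  invisible(x)
}

#' Gene-length-normalized TPM on TMM-scaled libraries
#'
#' Per sample, counts are converted to length rates `count / length`, the
#' effective library is the sum of rates times the sample's TMM factor, and
#' each gene's value is its rate over the effective library times 1e6. For a
#' factor of one a column sums exactly to 1e6; in general it sums to
#' `1e6 / factor`.
#'
#' @param counts An [expression_matrix()] with `layer = "counts"` and
#'   `gene_lengths` set.
#' @param factors A [tmm_factors()] object covering all samples (default:
#'   computed from `counts`).
#' @return An [expression_matrix()] with `layer = "tmm_tpm"`, gene lengths
#'   carried over.
#' @export
length_normalized_tpm <- function(counts, factors = tmm_factors(counts)) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$layer != "counts") stop("input must be the counts layer", call. = FALSE)
  if (is.null(counts$gene_lengths)) {
    stop("gene lengths are required for TPM", call. = FALSE)
  }
  stopifnot(inherits(factors, "TmmFactors"))
  f <- factors$factors[colnames(counts$values)]
  if (anyNA(f)) stop("TMM factors missing for some samples", call. = FALSE)
  rates <- counts$values / counts$gene_lengths
  eff_lib <- colSums(rates) * f
  if (any(eff_lib <= 0)) {
    stop("zero effective library for sample(s): ",
         paste(colnames(counts$values)[eff_lib <= 0], collapse = ", "),
         call. = FALSE)
  }
  tpm <- sweep(rates, 2, eff_lib, "/") * 1e6
  expression_matrix(tpm, layer = "tmm_tpm", gene_lengths = counts$gene_lengths)
}

#' Counts per 10,000 depth normalization for single cells
#'
#' Standard single-cell depth normalization ahead of log transformation and
#' module scoring: each cell's counts are scaled to sum to 10,000.
#'
#' @param counts An [expression_matrix()] with `layer = "counts"`.
#' @return An [expression_matrix()] tagged `"tmm_tpm"` (the package's layer
#'   tag for linear-scale depth-normalized abundances), usually passed
#'   straight to [log_transform()].
#' @export
counts_per_10k <- function(counts) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$layer != "counts") stop("input must be the counts layer", call. = FALSE)
  lib <- colSums(counts$values)
  if (any(lib <= 0)) {
    stop("cells with zero counts: ",
         paste(colnames(counts$values)[lib <= 0], collapse = ", "), call. = FALSE)
  }
  v <- sweep(counts$values, 2, lib, "/") * 1e4
  expression_matrix(v, layer = "tmm_tpm", gene_lengths = counts$gene_lengths)
}

#' Log transformation of normalized expression
#'
#' Applies `log2(x + 1)` and tags the result as the `log_norm` layer, the
#' layer expected by single-cell module scoring and marker testing.
#'
#' @param x An [expression_matrix()] with non-negative values.
#' @return An [expression_matrix()] with `layer = "log_norm"`.
#' @export
log_transform <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (any(x$values < 0)) stop("log transform requires non-negative values", call. = FALSE)
  expression_matrix(log2(x$values + 1), layer = "log_norm",
                    gene_lengths = x$gene_lengths)
}
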