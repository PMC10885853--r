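#' Read an expression matrix from disk
#'
#' Two on-disk layouts are supported:
#'
#' * `dense_tsv` — a dense table whose first column holds gene IDs and whose
#'   header row holds column IDs;
#' * `mtx` — a MatrixMarket triplet file with two sidecar files listing gene
#'   IDs (rows) and column IDs, one per line. MatrixMarket indices are
#'   1-based and are mapped onto the matrix rows/columns directly.
#'
#' Both layouts produce a `counts`-layer matrix; `NA` or negative entries are
#' hard errors.
#'
#' @param path Path to the dense table or the `.mtx` triplet file.
#' @param format `"dense_tsv"` or `"mtx"`.
#' @param genes_path,columns_path Sidecar paths (required for `"mtx"`).
#' @param sep Field separator for `dense_tsv` (default tab).
#' @return An [expression_matrix()] with `layer = "counts"`.
#' @export
read_matrix <- function(path, format = c("dense_tsv", "mtx"),
                        genes_path = NULL, columns_path = NULL, sep = "\t") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "dense_tsv") {
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df)
    if (!is.numeric(m)) stop("non-numeric values in expression table", call. = FALSE)
    if (anyNA(m)) stop("NA values are not permitted in expression input", call. = FALSE)
    if (any(m < 0)) stop("negative values are not permitted in counts", call. = FALSE)
    return(expression_matrix(m, layer = "counts"))
  }
  if (is.null(genes_path) || is.null(columns_path)) {
    stop("mtx format requires `genes_path` and `columns_path` sidecars",
         call. = FALSE)
  }
  mm <- Matrix::readMM(path)
  genes <- readLines(genes_path, warn = FALSE)
  cols <- readLines(columns_path, warn = FALSE)
  genes <- genes[nzchar(genes)]
  cols <- cols[nzchar(cols)]
  if (nrow(mm) != length(genes)) {
    stop(sprintf("mtx declares %d rows but gene sidecar lists %d genes",
                 nrow(mm), length(genes)), call. = FALSE)
  }
  if (ncol(mm) != length(cols)) {
    stop(sprintf("mtx declares %d columns but column sidecar lists %d IDs",
                 ncol(mm), length(cols)), call. = FALSE)
  }
  m <- as.matrix(mm)
  if (any(m < 0)) stop("negative values are not permitted in counts", call. = FALSE)
  dimnames(m) <- list(genes, cols)
  expression_matrix(m, layer = "counts")
}

#' Construct a score matrix
#'
#' Signatures-by-samples matrix of real-valued signature scores, tagged with
#' the expression layer the scores were computed on.
#'
#' @param values Numeric matrix, rownames = signature names, colnames =
#'   sample/cell IDs.
#' @param scored_layer Layer tag of the expression data that was scored.
#' @return An object of class `ScoreMatrix`.
#' @export
score_matrix <- function(values, scored_layer) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) > 0 && is.null(rownames(values))) {
    stop("score matrix needs signature rownames", call. = FALSE)
  }
  if (is.null(colnames(values))) stop("score matrix needs sample colnames", call. = FALSE)
  if (any(!is.finite(values))) stop("scores must be finite", call. = FALSE)
  structure(list(values = values, scored_layer = scored_layer),
            class = "ScoreMatrix")
}

#' @export
print.ScoreMatrix <- function(x, ...) {
  cat(sprintf("ScoreMatrix: %d signatures x %d samples [scored on %s]\n",
              nrow(x$values), ncol(x$values), x$scored_layer))
  invisible(x)
}

#' Construct a per-sample tumor purity table
#'
#' @param sample_id Character vector of unique sample IDs.
#' @param purity Cancer-cell fraction in `[0, 1]` per sample.
#' @param method Provenance tag, e.g. `"CPE"`, `"ABSOLUTE"`,
#'   `"simulated_truth"`.
#' @return A data frame of class `PurityTable` with columns `sample_id`,
#'   `purity` and attribute `method`.
#' @export
purity_table <- function(sample_id, purity, method = "simulated_truth") {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample IDs", call. = FALSE)
  purity <- as.numeric(purity)
  if (length(purity) != length(sample_id)) {
    stop("sample_id and purity lengths differ", call. = FALSE)
  }
  if (anyNA(purity) || any(purity < 0) || any(purity > 1)) {
    stop("purity must lie in [0, 1]", call. = FALSE)
  }
  out <- data.frame(sample_id = sample_id, purity = purity,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  class(out) <- c("PurityTable", "data.frame")
  out
}

CELL_TYPE_VOCABULARY <- c("malignant", "fibroblast", "myofibroblast",
                          "endothelial", "immune", "other")

#' Construct a per-cell type annotation
#'
#' @param cell_id Unique cell identifiers.
#' @param cell_type Cell type per cell, drawn from `vocabulary`.
#' @param dataset_id Label for the dataset of origin.
#' @param vocabulary Permitted cell-type labels.
#' @return A data frame of class `CellAnnotation` with columns `cell_id`,
#'   `cell_type`, and attributes `dataset_id`, `vocabulary`.
#' @export
cell_annotation <- function(cell_id, cell_type, dataset_id = "synthetic",
                            vocabulary = CELL_TYPE_VOCABULARY) {
  cell_id <- as.character(cell_id)
  cell_type <- as.character(cell_type)
  if (anyDuplicated(cell_id)) stop("duplicate cell IDs", call. = FALSE)
  if (length(cell_type) != length(cell_id)) {
    stop("cell_id and cell_type lengths differ", call. = FALSE)
  }
  bad <- setdiff(unique(cell_type), vocabulary)
  if (length(bad)) {
    stop("cell types outside vocabulary: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(cell_id = cell_id, cell_type = cell_type,
                    stringsAsFactors = FALSE)
  attr(out, "dataset_id") <- dataset_id
  attr(out, "vocabulary") <- vocabulary
  class(out) <- c("CellAnnotation", "data.frame")
  out
}

# -- result-table serialization -----------------------------------------------
# All result tables are written as TSV with a header row. Numerics are
# serialized with %.17g so a write/read round trip preserves doubles exactly;
# NA (e.g. an undefined coherence score) is written as the literal "NA".

fmt_cell <- function(x) {
  if (is.numeric(x)) {
    out <- vapply(x, function(v) if (is.na(v)) "NA" else sprintf("%.17g", v),
                  character(1))
  } else {
    out <- as.character(x)
    out[is.na(out)] <- "NA"
  }
  out
}

write_tsv_exact <- function(df, path) {
  cols <- lapply(df, fmt_cell)
  body <- do.call(paste, c(cols, sep = "\t"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (length(body)) writeLines(body, con)
  invisible(path)
}

#' Write a result table to TSV
#'
#' Generic writer for the package's result objects (score matrices,
#' coherence reports, association tables, plain data frames). Values round
#' trip exactly: reading the file back yields numerics equal to the originals
#' at full double precision.
#'
#' @param x Result object.
#' @param path Output path.
#' @param ... Unused.
#' @return Invisibly, `path`.
#' @export
write_table <- function(x, path, ...) UseMethod("write_table")

#' @export
write_table.data.frame <- function(x, path, ...) {
  write_tsv_exact(as.data.frame(x), path)
}

#' @export
write_table.ScoreMatrix <- function(x, path, ...) {
  sig_names <- rownames(x$values)
  if (is.null(sig_names)) sig_names <- character(0)
  df <- data.frame(signature = sig_names, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(x$values))) df[[colnames(x$values)[j]]] <- x$values[, j]
  write_tsv_exact(df, path)
}

#' Read a score matrix written by [write_table()]
#'
#' @param path Path to a score-matrix TSV.
#' @param scored_layer Layer tag to attach.
#' @return A [score_matrix()].
#' @export
read_score_matrix <- function(path, scored_layer = "tmm_tpm") {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (nrow(m) == 0) m <- matrix(0, 0, ncol(m), dimnames = list(NULL, colnames(m)))
  score_matrix(m, scored_layer = scored_layer)
}

#' Read a result table written by [write_table()]
#'
#' @param path Path to a TSV result table.
#' @return A data frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
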