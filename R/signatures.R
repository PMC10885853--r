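SIGNATURE_CATEGORIES <- c("EMT", "mesenchymal", "stemness", "cell_type",
                          "process", "other")

#' Construct a gene signature
#'
#' A named, categorized set of gene symbols. Categories follow the vocabulary
#' used throughout the package to separate EMT-related signatures from
#' cell-type and process signatures when summarizing purity associations.
#'
#' @param name Non-empty signature name.
#' @param genes Character vector of gene symbols; duplicates are removed.
#' @param category One of `"EMT"`, `"mesenchymal"`, `"stemness"`,
#'   `"cell_type"`, `"process"`, `"other"`.
#' @param source Free-text citation or provenance label.
#' @return An object of class `GeneSignature`.
#' @export
gene_signature <- function(name, genes, category = "other", source = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("signature name must be a non-empty string", call. = FALSE)
  }
  category <- match.arg(category, SIGNATURE_CATEGORIES)
  genes <- as.character(genes)
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("signature must contain at least one gene", call. = FALSE)
  genes <- unique(genes)
  structure(list(name = name, category = category, genes = genes,
                 source = source),
            class = "GeneSignature")
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat(sprintf("GeneSignature '%s' [%s]: %d genes\n", x$name, x$category,
              length(x$genes)))
  invisible(x)
}

#' Construct a signature collection
#'
#' @param signatures List of [gene_signature()] objects with unique names.
#' @return An object of class `SignatureCollection` (an ordered list).
#' @export
signature_collection <- function(signatures) {
  if (inherits(signatures, "GeneSignature")) signatures <- list(signatures)
  ok <- vapply(signatures, inherits, logical(1), "GeneSignature")
  if (!all(ok)) stop("all elements must be GeneSignature objects", call. = FALSE)
  nm <- vapply(signatures, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate signature names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  names(signatures) <- nm
  structure(signatures, class = "SignatureCollection")
}

#' @export
print.SignatureCollection <- function(x, ...) {
  cat(sprintf("SignatureCollection: %d signatures\n", length(x)))
  for (s in x) {
    cat(sprintf("  %-28s %-12s %4d genes\n", s$name, s$category,
                length(s$genes)))
  }
  invisible(x)
}

#' @export
`[.SignatureCollection` <- function(x, i) {
  signature_collection(unclass(x)[i])
}

#' Read gene signatures from a GMT file
#'
#' GMT is the tab-separated gene-set format: one set per line, fields
#' `name <tab> description <tab> gene1 <tab> gene2 ...`. When the description
#' field matches one of the package's category labels it is used as the
#' signature category; otherwise the category is `"other"` and the
#' description is kept as the `source`. Gene symbols are matched
#' case-sensitively and exactly everywhere in the package, so no case
#' normalization happens here.
#'
#' @param path Path to a GMT file.
#' @return A [signature_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sigs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(fields)), call. = FALSE)
    }
    name <- fields[[1]]
    desc <- fields[[2]]
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT line %d ('%s'): %d duplicate gene(s) removed",
                      i, name, sum(duplicated(genes))), call. = FALSE)
      genes <- unique(genes)
    }
    category <- if (desc %in% SIGNATURE_CATEGORIES) desc else "other"
    sigs[[i]] <- gene_signature(name, genes, category = category, source = desc)
  }
  nm <- vapply(sigs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate signature names in GMT file: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  signature_collection(sigs)
}

#' Write a signature collection to a GMT file
#'
#' @param coll A [signature_collection()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(coll, path) {
  stopifnot(inherits(coll, "SignatureCollection"))
  lines <- vapply(coll, function(s) {
    desc <- if (s$category != "other") s$category else if (nzchar(s$source)) s$source else "na"
    paste(c(s$name, desc, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
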