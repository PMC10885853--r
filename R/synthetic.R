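# Seeded generators for synthetic single-cell, pseudobulk, bulk, and
# subtype-labeled cohorts with known ground truth. These stand in for the
# consortium datasets the method is normally run on: discrete cell types with
# planted expression programs, bulk mixtures with known cancer-cell fraction,
# and subtype cohorts with planted up-regulated genes.

#' Configuration of the synthetic single-cell generator
#'
#' Counts are negative binomial: for cell `c` of type `t` and gene `g`,
#' `count ~ NB(mean = s_c * 2^(baseline_g + loading_{g,t}), dispersion)`,
#' where `s_c` is a log-normal per-cell library scale factor and
#' `baseline_g ~ Normal(baseline_logmean_mean, baseline_logmean_sd)` on the
#' log2 scale. Planted signatures assign an additive log2 loading to a gene
#' subset in selected cell types; the defaults plant an EMT-like program
#' (+2.5 log2 on fibroblasts and myofibroblasts) and a proliferation-like
#' control program (+2 log2 on malignant cells), mirroring the empirical
#' situation in which EMT signature genes have their highest expression in
#' stromal cell populations.
#'
#' @param n_genes Gene universe size (default 2000).
#' @param cells_per_type Named integer vector of cells per cell type.
#' @param baseline_logmean_mean,baseline_logmean_sd Normal parameters of the
#'   per-gene baseline log2 mean.
#' @param dispersion Negative binomial dispersion (default 0.3, typical of
#'   droplet scRNA-seq).
#' @param library_sdlog Log-normal sd of the per-cell library scale factor.
#' @param planted_signatures List of planted programs; each element a list
#'   with `n_genes`, `loading` (additive log2 effect), `cell_types`
#'   (character) and `category`.
#' @param gene_length_meanlog,gene_length_sdlog Log-normal parameters of the
#'   gene lengths carried on the matrix (bases).
#' @param seed Integer seed; the whole generation is a deterministic
#'   function of the config.
#' @return A list of class `CellProgramConfig`.
#' @export
cell_program_config <- function(n_genes = 2000,
                                cells_per_type = c(malignant = 500,
                                                   fibroblast = 500,
                                                   myofibroblast = 500,
                                                   endothelial = 500,
                                                   immune = 500),
                                baseline_logmean_mean = 1.5,
                                baseline_logmean_sd = 1.5,
                                dispersion = 0.3,
                                library_sdlog = 0.3,
                                planted_signatures = list(
                                  emt_like = list(
                                    n_genes = 50, loading = 2.5,
                                    cell_types = c("fibroblast", "myofibroblast"),
                                    category = "EMT"),
                                  proliferation_like = list(
                                    n_genes = 50, loading = 2.0,
                                    cell_types = "malignant",
                                    category = "process")),
                                gene_length_meanlog = log(1500),
                                gene_length_sdlog = 0.6,
                                seed = 1L) {
  if (is.null(names(cells_per_type)) || any(!nzchar(names(cells_per_type)))) {
    stop("cells_per_type must be named by cell type", call. = FALSE)
  }
  if (any(cells_per_type < 1)) stop("each cell type needs >= 1 cell", call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be positive", call. = FALSE)
  n_planted <- sum(vapply(planted_signatures, function(p) p$n_genes, numeric(1)))
  if (n_planted > n_genes) stop("planted gene sets exceed the gene universe", call. = FALSE)
  for (p in planted_signatures) {
    bad <- setdiff(p$cell_types, names(cells_per_type))
    if (length(bad)) stop("planted cell type(s) not generated: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes),
                 cells_per_type = cells_per_type,
                 baseline_logmean_mean = baseline_logmean_mean,
                 baseline_logmean_sd = baseline_logmean_sd,
                 dispersion = dispersion,
                 library_sdlog = library_sdlog,
                 planted_signatures = planted_signatures,
                 gene_length_meanlog = gene_length_meanlog,
                 gene_length_sdlog = gene_length_sdlog,
                 seed = as.integer(seed)),
            class = "CellProgramConfig")
}

# Deterministic pieces shared by the single-cell and bulk generators:
# baseline log2 means, gene lengths, planted gene assignment, and the
# gene x cell-type loading matrix. Drawn under the config seed.
program_truth <- function(cfg) {
  withr::with_seed(cfg$seed, {
    gene_ids <- sprintf("gene%04d", seq_len(cfg$n_genes))
    baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_logmean_mean,
                             cfg$baseline_logmean_sd)
    names(baseline) <- gene_ids
    gene_lengths <- stats::rlnorm(cfg$n_genes, cfg$gene_length_meanlog,
                                  cfg$gene_length_sdlog)
    names(gene_lengths) <- gene_ids
    types <- names(cfg$cells_per_type)
    loadings <- matrix(0, cfg$n_genes, length(types),
                       dimnames = list(gene_ids, types))
    pool <- sample(gene_ids)  # random disjoint assignment of planted genes
    sigs <- list()
    offset <- 0L
    for (nm in names(cfg$planted_signatures)) {
      p <- cfg$planted_signatures[[nm]]
      genes <- pool[(offset + 1L):(offset + p$n_genes)]
      offset <- offset + p$n_genes
      loadings[genes, p$cell_types] <- p$loading
      sigs[[nm]] <- gene_signature(nm, genes,
                                   category = p$category %||% "other",
                                   source = "planted synthetic program")
    }
    list(gene_ids = gene_ids, baseline = baseline,
         gene_lengths = gene_lengths, loadings = loadings,
         signatures = signature_collection(unname(sigs)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic single-cell cohort
#'
#' Draws negative binomial counts for discrete cell types under the model
#' described in [cell_program_config()]. The returned truth structure makes
#' every planted gene and loading recoverable, so recovery tests have exact
#' ground truth.
#'
#' @param cfg A [cell_program_config()].
#' @return A list with elements `expr` (counts [expression_matrix()] with
#'   gene lengths), `annotation` (a [cell_annotation()]), and `truth` (list:
#'   `baseline`, `loadings`, `signatures`, `library_factors`).
#' @export
generate_single_cell <- function(cfg = cell_program_config()) {
  stopifnot(inherits(cfg, "CellProgramConfig"))
  truth <- program_truth(cfg)
  types <- names(cfg$cells_per_type)
  n_cells <- sum(cfg$cells_per_type)
  cell_type <- rep(types, times = cfg$cells_per_type)
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  counts <- withr::with_seed(cfg$seed + 1L, {
    s <- stats::rlnorm(n_cells, meanlog = 0, sdlog = cfg$library_sdlog)
    m <- matrix(0L, cfg$n_genes, n_cells,
                dimnames = list(truth$gene_ids, cell_ids))
    for (t in types) {
      idx <- which(cell_type == t)
      mu_g <- 2^(truth$baseline + truth$loadings[, t])
      mu <- outer(mu_g, s[idx])
      m[, idx] <- stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion)
    }
    attr(m, "library_factors") <- s
    m
  })
  s <- attr(counts, "library_factors")
  attr(counts, "library_factors") <- NULL
  truth$library_factors <- stats::setNames(s, cell_ids)
  list(expr = expression_matrix(counts, layer = "counts",
                                gene_lengths = truth$gene_lengths),
       annotation = cell_annotation(cell_ids, cell_type,
                                    dataset_id = "synthetic_sc",
                                    vocabulary = union(CELL_TYPE_VOCABULARY,
                                                       types)),
       truth = truth)
}

#' Pseudobulk mixing design
#'
#' Twenty samples spanning fibroblast fractions from 20% to 80% on an evenly
#' spaced grid, the remainder malignant — the designed gradient used to show
#' that EMT-like scores track fibroblast content in mixtures of known
#' composition.
#'
#' @param n_samples Number of pseudobulk samples (default 20).
#' @param fraction_range Fibroblast fraction range `c(low, high)`
#'   (default `c(0.2, 0.8)`).
#' @param cells_per_sample Cells summed per pseudobulk sample (default 1000).
#' @param seed Integer seed for the cell sampling.
#' @return A list of class `PseudobulkDesign`.
#' @export
pseudobulk_design <- function(n_samples = 20, fraction_range = c(0.2, 0.8),
                              cells_per_sample = 1000, seed = 1L) {
  if (length(fraction_range) != 2 || fraction_range[1] > fraction_range[2] ||
      any(fraction_range < 0) || any(fraction_range > 1)) {
    stop("fraction_range must be c(low, high) within [0, 1]", call. = FALSE)
  }
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 fraction_range = fraction_range,
                 cells_per_sample = as.integer(cells_per_sample),
                 seed = as.integer(seed)),
            class = "PseudobulkDesign")
}

#' Build pseudobulk samples by mixing cell types at known fractions
#'
#' Per sample, the fibroblast fraction is taken from an evenly spaced grid
#' over `fraction_range` (`n_samples` points; a single sample uses the lower
#' bound); cells are sampled *with replacement* within each type to hit the
#' rounded per-type counts, and the pseudobulk profile is the per-gene sum
#' of the sampled cells' counts. The returned purity table records
#' `1 - fibroblast fraction` as simulated ground truth.
#'
#' @param sc Counts [expression_matrix()] of single cells.
#' @param ann A [cell_annotation()] covering the cells.
#' @param design A [pseudobulk_design()].
#' @return A list with `expr` (counts [expression_matrix()], gene lengths
#'   carried over), `purity` (a [purity_table()], method
#'   `"simulated_truth"`), and `fractions` (data frame of realized per-type
#'   cell counts).
#' @export
make_pseudobulk <- function(sc, ann, design = pseudobulk_design()) {
  stopifnot(inherits(sc, "ExpressionMatrix"), inherits(ann, "CellAnnotation"),
            inherits(design, "PseudobulkDesign"))
  if (sc$layer != "counts") stop("pseudobulk mixes raw counts", call. = FALSE)
  uncovered <- setdiff(em_columns(sc), ann$cell_id)
  if (length(uncovered)) {
    stop("annotation does not cover all cells (e.g. ", uncovered[1], ")",
         call. = FALSE)
  }
  type_of <- stats::setNames(ann$cell_type, ann$cell_id)[em_columns(sc)]
  fib_cells <- em_columns(sc)[type_of == "fibroblast"]
  mal_cells <- em_columns(sc)[type_of == "malignant"]
  if (!length(fib_cells)) stop("no fibroblast cells in annotation", call. = FALSE)
  if (!length(mal_cells)) stop("no malignant cells in annotation", call. = FALSE)
  fr <- design$fraction_range
  fracs <- if (design$n_samples == 1) fr[1] else
    seq(fr[1], fr[2], length.out = design$n_samples)
  ids <- sprintf("pseudobulk%02d", seq_len(design$n_samples))
  m <- withr::with_seed(design$seed, {
    out <- matrix(0, nrow(sc$values), design$n_samples,
                  dimnames = list(em_genes(sc), ids))
    for (i in seq_len(design$n_samples)) {
      n_fib <- round(fracs[i] * design$cells_per_sample)
      n_mal <- design$cells_per_sample - n_fib
      take <- c(
        if (n_fib > 0) fib_cells[sample.int(length(fib_cells), n_fib, replace = TRUE)],
        if (n_mal > 0) mal_cells[sample.int(length(mal_cells), n_mal, replace = TRUE)])
      out[, i] <- rowSums(sc$values[, take, drop = FALSE])
    }
    out
  })
  fractions <- data.frame(sample_id = ids, fibroblast_fraction = fracs,
                          n_fibroblast = round(fracs * design$cells_per_sample),
                          n_malignant = design$cells_per_sample -
                            round(fracs * design$cells_per_sample),
                          stringsAsFactors = FALSE)
  list(expr = expression_matrix(m, layer = "counts",
                                gene_lengths = sc$gene_lengths),
       purity = purity_table(ids, 1 - fracs, method = "simulated_truth"),
       fractions = fractions)
}

#' Configuration of the synthetic bulk tumor cohort
#'
#' Each tumor sample is a purity-weighted mixture of cell-type expected
#' expression profiles (malignant vs a fixed stromal composition), scaled to
#' a target library size, with negative binomial noise. NAT-like samples
#' (normal tissue adjacent to tumor) have purity 0 and a stroma-weighted
#' composition. The cell-type profiles come from the same program model as
#' the single-cell generator, so planted signatures behave consistently
#' across data modalities.
#'
#' @param n_samples Number of tumor samples (default 100).
#' @param n_nat Number of NAT samples, each paired to one tumor sample
#'   (default 20).
#' @param purity_range Tumor purity is drawn uniformly from this range
#'   (default `c(0.15, 0.95)`, matching the spread of consortium cohorts
#'   where maximal content is around 96%).
#' @param program A [cell_program_config()] defining the cell-type profiles.
#' @param stroma_composition Named non-negative weights (summing to 1) of the
#'   non-malignant fraction in tumor samples.
#' @param nat_composition Named weights of NAT sample composition.
#' @param library_size Expected total counts per sample (default 3e6).
#' @param dispersion Bulk negative binomial dispersion (default 0.05).
#' @param seed Integer seed.
#' @return A list of class `BulkCohortConfig`.
#' @export
bulk_cohort_config <- function(n_samples = 100, n_nat = 20,
                               purity_range = c(0.15, 0.95),
                               program = cell_program_config(),
                               stroma_composition = c(fibroblast = 0.50,
                                                      myofibroblast = 0.15,
                                                      endothelial = 0.15,
                                                      immune = 0.20),
                               nat_composition = c(fibroblast = 0.45,
                                                   myofibroblast = 0.10,
                                                   endothelial = 0.20,
                                                   immune = 0.25),
                               library_size = 3e6, dispersion = 0.05,
                               seed = 1L) {
  if (any(purity_range < 0) || any(purity_range > 1) ||
      purity_range[1] > purity_range[2]) {
    stop("purity_range must be c(low, high) within [0, 1]", call. = FALSE)
  }
  if (n_nat > n_samples) stop("n_nat cannot exceed n_samples", call. = FALSE)
  for (comp in list(stroma_composition, nat_composition)) {
    if (abs(sum(comp) - 1) > 1e-8 || any(comp < 0)) {
      stop("compositions must be non-negative and sum to 1", call. = FALSE)
    }
    bad <- setdiff(names(comp), names(program$cells_per_type))
    if (length(bad)) stop("composition names not in program cell types: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(n_samples = as.integer(n_samples), n_nat = as.integer(n_nat),
                 purity_range = purity_range, program = program,
                 stroma_composition = stroma_composition,
                 nat_composition = nat_composition,
                 library_size = library_size, dispersion = dispersion,
                 seed = as.integer(seed)),
            class = "BulkCohortConfig")
}

#' Generate a synthetic bulk cohort with known purity
#'
#' @param cfg A [bulk_cohort_config()].
#' @return A list with `expr` (counts [expression_matrix()] with gene
#'   lengths), `purity` (a [purity_table()] over all samples; NAT samples are
#'   recorded at purity 0), `nat` (named logical NAT flags), `pairing` (data
#'   frame `tumor`, `nat` of paired sample IDs), and `truth` (the program
#'   truth plus per-sample purity and the compositions).
#' @export
generate_bulk_cohort <- function(cfg = bulk_cohort_config()) {
  stopifnot(inherits(cfg, "BulkCohortConfig"))
  truth <- program_truth(cfg$program)
  types <- colnames(truth$loadings)
  # expected relative RNA composition of each cell type's transcriptome
  prof <- 2^(truth$baseline + truth$loadings)
  prof <- sweep(prof, 2, colSums(prof), "/")
  tumor_ids <- sprintf("tumor%03d", seq_len(cfg$n_samples))
  nat_ids <- if (cfg$n_nat > 0) sprintf("nat%03d", seq_len(cfg$n_nat)) else character(0)
  stroma_mix <- as.vector(prof[, names(cfg$stroma_composition), drop = FALSE] %*%
                            cfg$stroma_composition)
  nat_mix <- as.vector(prof[, names(cfg$nat_composition), drop = FALSE] %*%
                         cfg$nat_composition)
  res <- withr::with_seed(cfg$seed + 2L, {
    purity <- stats::runif(cfg$n_samples, cfg$purity_range[1], cfg$purity_range[2])
    m <- matrix(0, cfg$program$n_genes, cfg$n_samples + cfg$n_nat,
                dimnames = list(truth$gene_ids, c(tumor_ids, nat_ids)))
    for (i in seq_len(cfg$n_samples)) {
      w <- purity[i] * prof[, "malignant"] + (1 - purity[i]) * stroma_mix
      m[, i] <- stats::rnbinom(cfg$program$n_genes, mu = cfg$library_size * w,
                               size = 1 / cfg$dispersion)
    }
    for (j in seq_len(cfg$n_nat)) {
      m[, cfg$n_samples + j] <- stats::rnbinom(cfg$program$n_genes,
                                               mu = cfg$library_size * nat_mix,
                                               size = 1 / cfg$dispersion)
    }
    list(m = m, purity = purity)
  })
  all_ids <- c(tumor_ids, nat_ids)
  nat_flags <- stats::setNames(c(rep(FALSE, cfg$n_samples),
                                 rep(TRUE, cfg$n_nat)), all_ids)
  pairing <- if (cfg$n_nat > 0) {
    data.frame(tumor = tumor_ids[seq_len(cfg$n_nat)], nat = nat_ids,
               stringsAsFactors = FALSE)
  } else {
    data.frame(tumor = character(0), nat = character(0))
  }
  truth$purity <- stats::setNames(c(res$purity, rep(0, cfg$n_nat)), all_ids)
  truth$stroma_composition <- cfg$stroma_composition
  truth$nat_composition <- cfg$nat_composition
  list(expr = expression_matrix(res$m, layer = "counts",
                                gene_lengths = truth$gene_lengths),
       purity = purity_table(all_ids, truth$purity, method = "simulated_truth"),
       nat = nat_flags,
       pairing = pairing,
       truth = truth)
}

#' Configuration of the synthetic subtype-labeled cohort
#'
#' Emulates a subtype-labeled expression cohort (labels CMS1–CMS4 by
#' default) in which a known set of genes is up-regulated in one target
#' label. Default arm sizes give 100 target-label samples and 100 pooled
#' comparator samples, the design used for the planted-recovery experiments.
#'
#' @param n_per_label Named integer vector of samples per label.
#' @param n_genes Gene universe size.
#' @param planted Named list (by label) of `list(n_genes, log2fc)` planted
#'   up-regulation programs.
#' @param n_null_candidates Number of unperturbed genes added to the
#'   candidate list returned in the truth structure (default 200).
#' @param baseline_logmean_mean,baseline_logmean_sd Normal parameters of the
#'   per-gene baseline log2 mean counts.
#' @param dispersion Negative binomial dispersion (default 0.1).
#' @param seed Integer seed.
#' @return A list of class `SubtypeCohortConfig`.
#' @export
subtype_cohort_config <- function(n_per_label = c(CMS1 = 33, CMS2 = 33,
                                                  CMS3 = 34, CMS4 = 100),
                                  n_genes = 2000,
                                  planted = list(CMS4 = list(n_genes = 10,
                                                             log2fc = 3)),
                                  n_null_candidates = 200,
                                  baseline_logmean_mean = 5,
                                  baseline_logmean_sd = 1.5,
                                  dispersion = 0.1,
                                  seed = 1L) {
  if (length(n_per_label) < 2) stop("need at least 2 labels", call. = FALSE)
  if (any(n_per_label < 1)) {
    stop("label(s) with 0 samples: ",
         paste(names(n_per_label)[n_per_label < 1], collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(names(planted), names(n_per_label))
  if (length(bad)) stop("planted label(s) not in cohort: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  n_planted <- sum(vapply(planted, function(p) p$n_genes, numeric(1)))
  if (n_planted + n_null_candidates > n_genes) {
    stop("planted plus null candidate genes exceed the gene universe", call. = FALSE)
  }
  structure(list(n_per_label = n_per_label, n_genes = as.integer(n_genes),
                 planted = planted,
                 n_null_candidates = as.integer(n_null_candidates),
                 baseline_logmean_mean = baseline_logmean_mean,
                 baseline_logmean_sd = baseline_logmean_sd,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "SubtypeCohortConfig")
}

#' Generate a synthetic subtype-labeled cohort
#'
#' @param cfg A [subtype_cohort_config()].
#' @return A list with `expr` (counts [expression_matrix()]), `labels`
#'   (named character, sample to label), and `truth` (list: `planted_genes`
#'   per label, `candidates` — planted genes plus unperturbed null
#'   candidates — and `baseline`).
#' @export
generate_subtype_cohort <- function(cfg = subtype_cohort_config()) {
  stopifnot(inherits(cfg, "SubtypeCohortConfig"))
  withr::with_seed(cfg$seed, {
    gene_ids <- sprintf("gene%04d", seq_len(cfg$n_genes))
    baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_logmean_mean,
                             cfg$baseline_logmean_sd)
    names(baseline) <- gene_ids
    pool <- sample(gene_ids)
    planted_genes <- list()
    offset <- 0L
    for (lab in names(cfg$planted)) {
      k <- cfg$planted[[lab]]$n_genes
      planted_genes[[lab]] <- pool[(offset + 1L):(offset + k)]
      offset <- offset + k
    }
    null_candidates <- pool[(offset + 1L):(offset + cfg$n_null_candidates)]
    labels <- rep(names(cfg$n_per_label), times = cfg$n_per_label)
    n_samples <- length(labels)
    sample_ids <- sprintf("s%03d", seq_len(n_samples))
    names(labels) <- sample_ids
    m <- matrix(0, cfg$n_genes, n_samples,
                dimnames = list(gene_ids, sample_ids))
    for (lab in unique(labels)) {
      idx <- which(labels == lab)
      logmu <- baseline
      if (!is.null(planted_genes[[lab]])) {
        logmu[planted_genes[[lab]]] <- logmu[planted_genes[[lab]]] +
          cfg$planted[[lab]]$log2fc
      }
      mu <- matrix(2^logmu, cfg$n_genes, length(idx))
      m[, idx] <- stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion)
    }
    list(expr = expression_matrix(m, layer = "counts"),
         labels = labels,
         truth = list(planted_genes = planted_genes,
                      candidates = c(unlist(planted_genes, use.names = FALSE),
                                     null_candidates),
                      baseline = baseline))
  })
}
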