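# Independent oracles and small fixture builders used across the suite.

# Quick ExpressionMatrix from a bare matrix, adding names when missing.
make_em <- function(m, layer = "counts", gene_lengths = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%03d", seq_len(ncol(m)))
  expression_matrix(m, layer = layer, gene_lengths = gene_lengths)
}

# Brute-force coherence score: explicit loop over all unordered gene pairs.
brute_cs <- function(m, genes) {
  sub <- m[genes, , drop = FALSE]
  rs <- c()
  for (i in seq_len(nrow(sub) - 1)) {
    for (j in (i + 1):nrow(sub)) {
      rs <- c(rs, cor(sub[i, ], sub[j, ]))
    }
  }
  mean(rs)
}

# Hand-coded trimmed-mean-of-M-values factors: reference selection by the
# 75th-percentile-to-library-size ratio, M/A statistics over doubly positive
# genes, rank-based double trimming, precision-weighted mean of retained M,
# geometric-mean rescaling. Written directly from the algorithm definition,
# independently of the package's implementation path.
brute_tmm_factors <- function(x, trim_m = 0.3, trim_a = 0.05,
                              a_cutoff = -1e10) {
  lib <- colSums(x)
  f75 <- apply(x, 2, quantile, probs = 0.75, names = FALSE) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  one_factor <- function(j) {
    obs <- x[, j]
    refc <- x[, ref]
    nO <- lib[j]
    nR <- lib[ref]
    logR <- log2((obs / nO) / (refc / nR))
    absE <- (log2(obs / nO) + log2(refc / nR)) / 2
    v <- (nO - obs) / (nO * obs) + (nR - refc) / (nR * refc)
    fin <- is.finite(logR) & is.finite(absE) & (absE > a_cutoff)
    logR <- logR[fin]
    absE <- absE[fin]
    v <- v[fin]
    if (!length(logR) || max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * trim_m) + 1
    hiL <- n + 1 - loL
    loS <- floor(n * trim_a) + 1
    hiS <- n + 1 - loS
    keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
      (rank(absE) >= loS & rank(absE) <= hiS)
    f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
    if (!is.finite(f)) f <- 0
    2^f
  }
  fac <- vapply(seq_len(ncol(x)), one_factor, numeric(1))
  fac <- fac / exp(mean(log(fac)))
  names(fac) <- colnames(x)
  fac
}

# A deterministic 10-gene, 3-sample count fixture with unequal compositions
# (so TMM factors differ from 1) and no zeros.
tmm_fixture <- function() {
  m <- matrix(c(
    120,  240,  60,
    500,  950,  510,
    80,   160,  85,
    1000, 2100, 980,
    300,  610,  310,
    45,   95,   40,
    700,  1350, 720,
    210,  400,  220,
    55,   120,  50,
    2000, 3900, 2100), nrow = 10, byrow = TRUE,
    dimnames = list(sprintf("g%02d", 1:10), c("A", "B", "C")))
  m
}
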