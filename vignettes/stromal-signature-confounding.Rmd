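---
title: "Methods: stromal confounding of EMT-related signature scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stromal confounding of EMT-related signature scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromasig)
```

## The problem and the model

Bulk tumor RNA-seq mixes transcripts from cancer cells with those of
fibroblasts, myofibroblasts, endothelial and immune cells. A gene-set score
computed on such a mixture confounds two things: the activity of the
program inside cancer cells, and the fraction of the sample occupied by
cell types that constitutively express the program's genes. EMT,
mesenchymal and stemness signatures are particularly exposed because
collagen, matrix and mesenchymal-marker genes are fibroblast staples.

`stromasig` implements the analysis chain that separates these two
explanations, and a set of synthetic generators that make every step
testable against planted ground truth. The package treats the bulk profile
of a sample with cancer-cell fraction (purity) $p$ as a mixture

$$\mu_g(p) \;=\; p\,\pi_g^{\mathrm{mal}} \;+\; (1-p)\sum_t w_t\,\pi_g^{t},$$

where $\pi^t$ is the expected relative transcriptome of cell type $t$ and
$w_t$ the composition of the non-malignant fraction. Counts are negative
binomial around $\mu_g(p)$ scaled to the library size. A signature planted
on stromal types then has a bulk score that is, in expectation, a
decreasing linear function of purity — the signature behaves exactly like
the confounded EMT signatures in real cohorts, by construction.

## Signature scoring

**Bulk.** The score of signature $S$ in sample $j$ is the arithmetic mean
of TPM values over the genes of $S$ present in the matrix. TPM is computed
from counts with gene-length normalization on TMM-scaled libraries
(edgeR's trimmed mean of M-values with the canonical defaults: log-ratio
trim 0.3, abundance trim 0.05, precision weighting, factors rescaled to
geometric mean 1). The mean is taken on the linear TPM scale by default; a
`use_log` flag exposes the log-scale alternative because the field uses
both conventions and the choice is not derivable from the score's
definition. A signature must have at least `min_genes = 3` genes present.

**Single cell.** Per-cell scores use the control-adjusted module-score
convention: all genes are ranked by mean expression across cells and cut
into `n_bins = 24` equal-frequency bins (ties broken by stable gene order,
for determinism); each signature gene contributes `n_ctrl = 100` control
genes drawn uniformly *with replacement* from its own bin under a fixed
seed; the score is the mean expression of signature genes minus the mean
of the pooled control draws. Subtracting bin-matched controls removes the
cell's overall expression level, so a random gene set scores about zero
(the suite checks $|\text{mean score}| \le 0.05$ over 500+ cells) and a
set of genes whose controls share their exact profiles scores exactly
zero. Single-cell matrices are depth-normalized to counts per 10,000 and
transformed as $\log_2(x+1)$ before scoring and marker testing.

## The coherence score and its calibration

The coherence score of a signature in a dataset is the mean Pearson
correlation over all unordered gene pairs,

$$\mathrm{CS} = \binom{n}{2}^{-1} \sum_{i<j} r(g_i, g_j),$$

computed after dropping zero-variance genes (a correlation with a
constant profile is undefined; dropping is recorded in `n_genes_used`).
When fewer than `min_genes` usable genes remain the CS is *undefined* and
reported as `NA` rather than raised as an error, so collections of
hundreds of signatures can be screened in one pass.

Signatures pass the screen when CS > 0.18 (strict). The package
calibrates this operating point rather than deriving it: under a null of
2,000 mutually independent standard-normal genes across 380 samples, the
CS of a random 5-gene set has standard deviation about 0.016, so 0.18 sits
more than ten standard deviations out and the permutation tail probability
is far below 0.01. Larger sets concentrate harder, so the same threshold
is more stringent for realistic signature sizes. `scripts/acceptance.R`
recomputes this tail probability from scratch.

The permutation null (`coherence_null`) draws equal-size gene sets from
the *same* dataset, preserving its background correlation structure — a
dataset-conditional null rather than an independence null. P-values use
the add-one upper-tail estimator $(1 + \#\{CS_0 \ge CS\})/(1 + B)$, which
is never zero and is uniform under the null up to discreteness (the suite
checks the fraction of $P \le 0.05$ lies in $[0.02, 0.10]$ over 200 null
signatures).

Whether CS should be computed on linear or log expression is not fixed by
its definition; the package computes it on the layer the caller provides
and the pipeline uses the same layer it scores on (linear TMM-TPM), for
internal consistency.

## Redundancy filtering

Collections of published signatures contain near-duplicates. A greedy
pass in collection order drops any signature whose Jaccard index with an
already retained signature exceeds 0.25; explicitly protected names are
never dropped. Greedy-in-order is a convention (the filter's outcome can
depend on order); it is deterministic and idempotent, both of which the
suite asserts.

## Purity association

Scores are correlated with purity by Pearson correlation over the sample
intersection. Families of signatures are compared with a one-sided
Wilcoxon rank-sum test; the reported effect size is $|Z|/\sqrt{N}$, which
lives on the 0–1 scale customary for rank tests on cohort data, and the
rank-biserial correlation $1 - 2U/(n_1 n_2)$ is reported alongside (it
reaches exactly 1 at complete separation, which the primary estimator
does not).

Purity groups use the 25th/75th percentiles of tumor purity with an
at-or-beyond rule for ties; NAT samples are NAT regardless of recorded
purity. Group tests are one-sided by design — the hypothesis is
directional (stromally driven scores are *higher* in low-purity and NAT
samples): a two-sample *t* for T_low vs T_high and a paired *t* for NAT
vs T_high over complete pairs. The Bonferroni family is every test
actually performed in one output table (signatures × comparisons), the
analogue of adjusting within one figure. Stars map adjusted P as
`<1e-15 = ****`, `<1e-4 = ***`, `<0.001 = **`, `<0.05 = *`; the `****`
cut implements "printed as zero" as below double-precision resolution.

## Single-cell attribution

Marker testing between two cell types is a per-gene two-sided Wilcoxon
rank-sum on log-normalized values, using the tie-corrected normal
approximation with continuity correction (the large-sample path of
`stats::wilcox.test`, vectorized; the suite checks agreement with the
reference implementation gene by gene). The fold change is the ratio of
de-logged group means with a pseudocount of 1, reported as log2; a gene
passes in a direction when FC ≥ 2 that way (inclusive boundary) *and*
P < 1e-10. The P threshold reads the conventional "10e-10" notation as
$10^{-10}$. A signature's attribution is the percentage of its available
genes passing toward fibroblasts vs toward malignant cells; several
datasets pool by union (available in any, passed in any), the most
permissive of the defensible pooling rules and the one that treats "is
this gene ever fibroblast-dominant" as the question of interest.

Dot statistics per cell type report the mean module score and the
fraction of cells with a strictly positive score; "score > 0" is the
positivity convention, chosen because the module score is centered by
construction. Cell types with no cells are flagged unavailable rather
than dropped.

## Synthetic data: what it emulates, and what it does not

The single-cell generator draws
$\mathrm{count}_{gc} \sim \mathrm{NB}\!\big(s_c\,2^{\beta_g + \lambda_{g,t(c)}},\ \phi\big)$
with per-gene baselines $\beta_g \sim N(1.5, 1.5^2)$ (log2 scale),
log-normal per-cell library factors (sdlog 0.3), dispersion $\phi = 0.3$,
and additive log2 loadings $\lambda$ for planted programs. Defaults: 2,000
genes; five cell types (malignant, fibroblast, myofibroblast,
endothelial, immune) at 500 cells each; an EMT-like program of 50 genes at
+2.5 log2 on fibroblasts and myofibroblasts; a proliferation-like control
of 50 genes at +2 log2 on malignant cells. These are desk-scale values
with effects comfortably above the marker thresholds, chosen once as the
study conditions. Gene lengths are log-normal (median 1.5 kb) and ride
along for TPM.

Pseudobulk samples take an evenly spaced fibroblast-fraction grid
(20–80 %, 20 samples, 1,000 cells each), sample cells with replacement
within type, and sum raw counts. Summing without per-type mRNA-content
scaling keeps the mixture linear in cell numbers, which the monotonicity
tests rely on; the grid (rather than uniform draws) makes the designed
gradient deterministic. Cells-per-sample and with-replacement sampling
are conventions recorded in the design object.

The bulk generator mixes expected cell-type profiles by purity (uniform
on [0.15, 0.95], matching cohorts whose maximal content is near 96 %),
at library size 3e6 and dispersion 0.05; NAT samples have purity 0 and a
stroma-weighted composition, paired one-to-one with the first tumor
samples. The subtype generator plants 10 up-genes at log2 effect 3 in the
target label, with default arm sizes 100 (CMS4) vs 100 (CMS1–3 pooled) so
both arms of the recovery experiment have 100 samples; 200 unperturbed
candidates provide the false-positive denominator.

What the generators deliberately omit: doublets, ambient RNA, batch
effects, continuous EMT trajectories within malignant cells, cell-type
specific mRNA content, and gene-gene correlation beyond the planted
programs. Passing tests therefore demonstrate that the *pipeline*
recovers planted structure under clean mixture assumptions — not that any
particular real signature is or is not confounded; on real data the
marker thresholds and coherence screen face heavier tails and correlated
backgrounds than these nulls.

## Subtype proxy derivation

Candidate extraction from classifier internals (importance tables,
template genes) is treated as input data, not re-implemented: it reads
third-party model objects and is a list of symbols, not an algorithm. The
derivation itself is a one-sided Welch *t* test (target label greater) on
$\log_2(x+1)$ values — Welch because no equal-variance assumption is
warranted across subtypes — with log2FC as the difference of log2-scale
group means, Benjamini–Hochberg adjustment over the tested candidates
("adjusted P" without a named method is taken as the field-default BH),
and the joint filter log2FC > 2 (strict) with adjusted P < 0.05. The
result records the full per-candidate test table; an empty derivation is
a valid outcome (the shuffled-label control expects it).

## Numerical choices and degenerate inputs

* Missing values in expression layers are hard errors; correlations and
  means are undefined on NA and silent propagation would poison every
  downstream table.
* Gene symbols match case-sensitively and exactly; alias resolution is
  data, not code.
* Result tables serialize numerics as `%.17g`, so write/read round trips
  are exact at double precision; undefined values serialize as `NA`.
* All randomness is seeded and scoped (`withr::with_seed`), so no
  function disturbs the caller's RNG state and the full pipeline is
  byte-deterministic for a fixed seed.
* TMM factors are rescaled to geometric mean exactly 1; the reference
  library is the one whose 75th-percentile/library-size ratio is closest
  to the mean of those ratios.
* An all-zero sample is a hard error in TPM (zero effective library), as
  is a sample sharing no non-zero genes with the TMM reference.

## Problem sizes

The shipped analyses and the test suite run at the study's desk scale:
2,000 genes, 2,500 cells, 100-sample bulk cohorts, 10,000-draw
permutation nulls, 100-run recovery experiments. These sizes put every
Monte-Carlo estimate well inside its stated tolerance band while keeping
the whole suite in the order of a minute on one CPU; they are the
package's reference conditions, and the generators accept larger values
unchanged.

## Known limitations

* The mixture model is linear in cell counts; real bulk profiles include
  cell-type mRNA-content differences and compositional normalization
  interactions that can attenuate or inflate purity correlations.
* The coherence null conditions on one dataset; transferring a CS
  threshold across datasets with very different correlation backgrounds
  is an extrapolation.
* The greedy redundancy filter is order-dependent by design; a different
  collection order can keep a different representative of a redundant
  clique.
* Family effect sizes from rank tests saturate below 1 with unequal group
  sizes; the rank-biserial column should be used when "complete
  separation" needs to be read off.
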