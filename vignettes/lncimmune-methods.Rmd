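---
title: "Methods: mapping lncRNA-immune interactions in tumor cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping lncRNA-immune interactions in tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncimmune)
```

# Overview

`lncimmune` implements an integrated analysis of long non-coding RNAs
(lncRNAs) and the tumor immune microenvironment in bulk RNA-seq cohorts with
paired tumor/normal samples, of the kind produced for prostate
adenocarcinoma by TCGA-style projects. The pipeline runs, in order:

1. **Normalization** of raw counts to FPKM and lncRNA prevalence profiling.
2. **Differential expression** of lncRNAs between tumor and normal with a
   negative-binomial Wald test (fold change > 1.5 and BH-FDR < 0.05).
3. **Prognostic screening** of differential lncRNAs: univariate Cox
   regression plus a median-split Kaplan-Meier / log-rank companion, per
   endpoint (overall and disease-free survival).
4. **Per-sample gene-set activity** for hallmark and immune-process
   collections via a GSVA-style kernel-CDF rank random walk.
5. **Partner-set enrichment**: each lncRNA's significantly correlated
   protein-coding genes (|Rs| > 0.3, FDR < 0.05) are tested for
   over-representation in each gene set with a one-sided exact test
   (OR > 1, FDR < 0.05).
6. **Track correlations** with supplied immunogenomic signature scores,
   deconvolved immune-cell fractions, and immune checkpoint genes.
7. **Mediation edges and summary tables** backing network / bubble / grid
   views.

Every stage is exposed as a data-frame-first function returning a tibble,
so results chain with the pipe; the `run_pipeline()` orchestrator
serializes each stage as TSV before starting the next.

# The statistical engines

## Negative-binomial differential expression

Counts are modeled as NB with `Var = mu + alpha * mu^2`. Size factors are
median-of-ratios over genes with all-positive counts. The per-gene
dispersion `alpha` is a pooled within-group method-of-moments estimate on
normalized counts, floored at `1e-8`. The Wald statistic contrasts the
log2 ratio of group means with a delta-method standard error derived from
the NB variance function, and p-values are BH-adjusted over the genes that
pass independent filtering (mean normalized count >= 1; filtered genes are
excluded from the BH family). The fold-change gate is symmetric: `up`
needs FC > 1.5, `down` needs FC < 1/1.5, both at FDR < 0.05. Raw (not
shrunken) fold changes are thresholded. Shrinkage, outlier refitting and
weighting are deliberately out of scope; acceptance is by planted-truth
recovery, and the null calibration of this test is verified on simulated
global-null cohorts (raw p < 0.05 rate within 99% binomial bounds of 0.05
at ~2,500 genes).

## Survival screening

Cox models are fitted by partial likelihood with the Efron tie correction
(via the survival package); a monotone-likelihood fit is flagged and
excluded from ranking instead of reporting a spurious finite hazard ratio.
Median dichotomization sends ties at the median to the low group — a
deterministic rule that keeps both groups non-empty for any non-constant
vector. Prognosis labels (`good`: HR < 1, `bad`: HR > 1) use the raw Cox
p < 0.05, mirroring the convention of reporting unadjusted log-rank
p-values for individual genes; a BH-adjusted column is emitted alongside.
The expression filter keeps genes with median FPKM above 1 (median, not
mean, so a few extreme samples cannot rescue an unexpressed gene).

## Gene-set scoring

For each gene a Gaussian-kernel CDF across samples (bandwidth `sd/4`,
floored for constant rows) turns expression into quantile positions; per
sample, genes are ranked by these positions, weighted `|N/2 - r|^tau`
(`tau = 1`), and a weighted Kolmogorov-Smirnov walk steps up at set genes
and down elsewhere. The score is the maximum positive plus maximum
negative deviation ("maxdiff"). Input is `log2(FPKM + 1)`; the offset
avoids `log(0)` and the log makes the kernel's roughly-symmetric
assumption tenable. Scores are exactly invariant to per-gene positive
affine transforms (the walk consumes only standardized CDF positions);
invariance under general nonlinear monotone transforms is only approximate
for the Gaussian kernel, because such transforms can reorder kernel-CDF
values across genes — an intrinsic property of the kernel variant, not an
implementation artifact. The implementation is checked against a literal
step-by-step enumeration of the walk on small instances.

## Partner sets and enrichment

Spearman correlations use average ranks and the t approximation
`t = Rs * sqrt((n-2)/(1-Rs^2))`. BH families are deliberately scoped:
per-lncRNA for partner screens, per-collection for enrichment, per-call
for track correlations; each record carries its family. The one-sided
exact enrichment p-value is the upper hypergeometric tail `P(X >= a)` —
identical for "Fisher's exact test" and "hypergeometric test" naming, and
both names are accepted. The odds ratio uses the Haldane-Anscombe +0.5 on
all cells only when a zero cell occurs, and only for display/gating —
never inside the exact tail. The universe for enrichment is the expressed
protein-coding genes entering the correlation screen; lncRNAs are excluded
from it because the hallmark and immune-process collections are
coding-gene sets.

## Deconvolution

Cell fractions are estimated by non-negative least squares per sample over
the shared signature genes, followed by renormalization to proportions,
rather than by the nu-SVR machinery of CIBERSORT; the per-sample relative
residual is recorded. NNLS is
deterministic, dependency-light, exact on noiseless mixtures, and
scale-invariant in the mixture after renormalization. It runs on
linear-scale expression (FPKM), never log. The 22 LM22 cell-type names are
shipped (`lm22_cell_types()`); a synthetic block-marker signature matrix
stands in for the real LM22 matrix, which cannot be redistributed here.

# The synthetic cohort generator

`simulate_cohort()` is a first-class module, not a fixture: it emulates
the *inputs* of the real study (counts, annotation, clinical table,
hallmark/immune-process GMTs, signature-score tracks, signature matrix)
with planted ground truth for every downstream stage.

Key modeling choices, each made once:

* **NB counts** with log-normal gene dispersions (`meanlog = log(0.1)`,
  `sdlog = 0.5`), lncRNA baselines ~2 log2 units below coding genes, and
  gene lengths log-uniform on [200 bp, 100 kb].
* **Pairing** through a patient-level multiplicative effect (log2 SD 0.3)
  shared by each tumor/normal pair. Because it scales all genes of a
  sample equally, median-of-ratios normalization absorbs it; it emulates
  paired designs without full patient covariates.
* **Latent immune-activity factors** are standard normal per sample with a
  one-SD higher mean in tumors: immune programs run hotter in tumor
  tissue, so a factor-coupled lncRNA is itself differential with effective
  log2FC equal to `sign * coupling_strength`, which is what its truth
  record stores. Coupled lncRNAs, their module genes and the checkpoint
  genes load on these factors; signature-score tracks follow them.
* **Couplings and prognostic effects are planted on well-expressed
  lncRNAs** (sampled from the top of the baseline-expression ranking of
  the eligible pool): an immune- or prognosis-linked lncRNA must be
  measurable to be discoverable, and planting signal on a gene below the
  detection filter would only test the filter.
* **Immune mixing** applies to *every* sample (tumors and normals draw
  Dirichlet(1,...,1) fractions): normal tissue also carries an immune
  infiltrate, and making marker expression condition-dependent would
  induce a library-composition artifact in size factors. The signature
  block is scaled to stay a minor share of the library for the same
  reason; markers run ~100x over background, which keeps the matrix
  well-conditioned for NNLS.
* **Survival** is exponential with log hazard `sum(beta * z(expr))` over
  the planted prognostic genes (standardized observed log2 expression),
  with exponential censoring whose rate is matched to the target censoring
  fraction (exact under a null effect). Because genes correlate through
  patient effects and shared factors, non-planted genes can legitimately
  inherit prognostic association — as co-expressed genes do in real
  cohorts; sign consistency of the planted genes is what the tests pin.

The default shape (100 tumors / 20 paired normals, 500 lncRNAs / 2,000
coding genes, 22 cell types, 26 signature tracks, 50 + 95 gene sets) is a
desk-scale miniature of a PRAD-like cohort (499 tumor / 52 paired normal);
every dimension is configurable up to the full cohort scale.

What the generator does **not** emulate: isoform structure, GC/length
biases beyond the FPKM definition, tumor purity as an explicit covariate,
copy-number or mutation processes behind the signature tracks (tracks are
emitted as numeric scores directly), and batch effects. Passing tests
therefore demonstrate algorithmic correctness and calibration under a
clean generative model — not robustness to every artifact of real TCGA
data.

# Numerical choices and degenerate inputs

* Constant expression vectors: correlation returns an `NA` sentinel and is
  excluded from BH families; median dichotomization errors; GSVA floors
  the bandwidth at `1e-6`.
* Zero group means in DE get a half-normalized-count floor so the log fold
  change stays defined; all-zero rows are dropped and counted.
* Ties: average ranks in Spearman; Efron in Cox; median ties to "low";
  Wilcoxon switches from exact enumeration to the tie-corrected normal
  approximation when either group exceeds 10.
* Exact-test tail: `P(X >= a)` computed from the hypergeometric survival
  function; verified against `choose()`-based enumeration for every table
  with total at most 30.
* Non-negative least squares: if a sample's fit returns an all-zero
  coefficient vector, fractions fall back to uniform (the residual then
  flags the sample).

# Problem sizes used by the test and acceptance runs

Unit and property tests run on cohorts of 20-100 tumors and 500-900 genes.
Calibration checks use the default-shape null cohort (~2,500 genes, 80,000
lncRNA-gene pairs). Recovery checks use 50/50 for DE power, 200 tumors for
Cox bias (200 generator draws), 200 tumors for enrichment recovery, and 50
samples for deconvolution. The end-to-end demonstration cohort uses 300
tumors / 50 normals so that each sequential gate (DE, then partners, then
enrichment) retains its stated power for the planted couplings; at the
default desk scale the DE gate sits at the edge of power for
factor-coupled lncRNAs, which is a property of the scaled-down design
rather than of the method.

# Known limitations

* The NB Wald test with moment dispersions is less powerful than
  shrinkage-based estimators at very small sample sizes; it is, however,
  well calibrated under the null, which is the property the pipeline's
  gates rely on.
* The enrichment procedure conditions on the partner gate; genes just
  below |Rs| = 0.3 contribute nothing. With very few significant partners
  the one-sided exact test is conservative by construction.
* NNLS deconvolution reports relative fractions only, and inherits the
  identifiability of the supplied signature matrix (checked for full
  column rank).
* Signature-score tracks are passed through, not recomputed; sample-id
  alignment is the caller's responsibility up to the 50% overlap guard.
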