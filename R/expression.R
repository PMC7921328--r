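#' Convert raw counts to FPKM
#'
#' FPKM (fragments per kilobase of transcript per million mapped reads):
#' `FPKM[i, j] = counts[i, j] * 1e9 / (length[i] * libsize[j])` with
#' `libsize[j]` the column sum of counts. The identity
#' `sum_i FPKM[i, j] * length[i] = 1e9` holds for every sample.
#'
#' @param counts Gene x sample count matrix (unit `"counts"`).
#' @param lengths Named numeric vector of transcript lengths in bp covering
#'   all rows of `counts`, or a data frame with `gene_id` and `length_bp`.
#' @return FPKM matrix tagged with unit `"FPKM"`.
#' @examples
#' m <- matrix(c(10, 0), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' to_fpkm(expression_matrix(m, "counts"), c(a = 1000, b = 500))
#' @export
to_fpkm <- function(counts, lengths) {
  assert_unit(counts, "counts")
  if (is.data.frame(lengths)) {
    lengths <- setNames(lengths$length_bp, lengths$gene_id)
  }
  len <- lengths[rownames(counts)]
  if (anyNA(len)) stop_input("lengths missing for %d genes", sum(is.na(len)))
  if (any(len <= 0)) stop_input("gene lengths must be positive")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop_input("zero library size in sample(s): %s",
               paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  fpkm <- counts / len * rep(1e9 / lib, each = nrow(counts))
  expression_matrix(fpkm, "FPKM")
}

#' Expression-matrix constructor
#'
#' Tags a gene x sample numeric matrix with its unit so downstream stages can
#' verify they receive the scale they expect.
#'
#' @param values Numeric matrix with gene row names and sample column names.
#' @param unit One of `"counts"`, `"FPKM"`, `"log2FPKM"`.
#' @return The matrix with an `expr_unit` attribute.
#' @export
as_expression_matrix <- function(values, unit = c("counts", "FPKM", "log2FPKM")) {
  expression_matrix(values, match.arg(unit))
}

#' Profile lncRNA expression prevalence
#'
#' For each FPKM cutoff, the fraction of genes (of the selected biotype)
#' detected above the cutoff in at least one sample, the mean per-sample
#' detected fraction, and the fractions of genes detected in more than
#' `broad_fraction` and in fewer than `narrow_fraction` of samples.
#'
#' @param fpkm FPKM matrix.
#' @param annotation Tibble with `gene_id` and `biotype`.
#' @param biotype Biotype to profile (default `"lncRNA"`).
#' @param cutoffs FPKM detection cutoffs.
#' @param broad_fraction,narrow_fraction Sample-fraction thresholds for the
#'   broadly / narrowly detected summaries.
#' @return Tibble with one row per cutoff: `cutoff`, `frac_detected_any`,
#'   `mean_frac_samples`, `frac_broad`, `frac_narrow`.
#' @export
prevalence_profile <- function(fpkm, annotation, biotype = "lncRNA",
                               cutoffs = c(0.1, 1),
                               broad_fraction = 0.9, narrow_fraction = 0.1) {
  assert_unit(fpkm, "FPKM")
  keep <- annotation$gene_id[annotation$biotype == biotype]
  keep <- intersect(rownames(fpkm), keep)
  if (length(keep) == 0L) stop_input("no genes of biotype '%s' in the matrix", biotype)
  m <- fpkm[keep, , drop = FALSE]
  n_samp <- ncol(m)
  purrr::map_dfr(cutoffs, function(co) {
    det <- m >= co
    frac_samples <- rowMeans(det)
    tibble::tibble(
      cutoff = co,
      frac_detected_any = mean(rowSums(det) > 0),
      mean_frac_samples = mean(frac_samples),
      frac_broad = mean(frac_samples > broad_fraction),
      frac_narrow = mean(frac_samples < narrow_fraction)
    )
  })
}

# median-of-ratios size factors over genes with all-positive counts
size_factors <- function(counts) {
  pos <- rowSums(counts == 0) == 0
  if (sum(pos) < 1L) stop_input("no gene has all-positive counts; cannot compute size factors")
  lg <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- exp(apply(lg - ref, 2, median))
  sf / exp(mean(log(sf)))
}

#' Differential expression by a negative-binomial Wald test
#'
#' Two-group differential expression on raw counts: median-of-ratios size
#' factors, per-gene method-of-moments dispersion on normalized counts
#' (floored at 1e-8), and a Wald test of log2 fold change = 0 whose standard
#' error comes from the NB variance function `Var = mu + alpha * mu^2`.
#' Genes with mean normalized count below `min_mean` are excluded from
#' testing and from the Benjamini-Hochberg family (independent filtering);
#' all-zero rows are excluded silently and reported in `glance()`.
#'
#' Calls use a symmetric fold-change gate: `up` if `FC > fc_gate` and
#' `FDR < fdr_gate`, `down` if `FC < 1/fc_gate` and `FDR < fdr_gate`, else
#' `ns`.
#'
#' @param counts Gene x sample count matrix (unit `"counts"`).
#' @param condition Character/factor vector over samples with values
#'   `"tumor"`/`"normal"` (or any two levels; the first level of
#'   `ref_level` is the baseline).
#' @param ref_level Baseline condition level (default `"normal"`).
#' @param min_mean Independent-filter threshold on the mean normalized count.
#' @param fc_gate,fdr_gate Call gates (defaults 1.5 and 0.05).
#' @return Object of class `lnc_de`; `tidy()` returns the per-gene table
#'   (`gene_id`, `base_mean`, `mean_ref`, `mean_alt`, `log2fc`, `se`, `p`,
#'   `fdr`, `call`), `glance()` a one-row run summary.
#' @export
differential_expression <- function(counts, condition, ref_level = "normal",
                                    min_mean = 1, fc_gate = 1.5, fdr_gate = 0.05) {
  assert_unit(counts, "counts")
  condition <- as.character(condition)
  if (length(condition) != ncol(counts)) {
    stop_input("`condition` must have one entry per sample column")
  }
  lev <- unique(condition)
  if (length(lev) != 2L) stop_input("exactly two condition levels required, got %d", length(lev))
  if (!ref_level %in% lev) stop_input("ref_level '%s' not present", ref_level)
  alt_level <- setdiff(lev, ref_level)
  n1 <- sum(condition == ref_level); n2 <- sum(condition == alt_level)
  if (n1 < 2L || n2 < 2L) stop_input("each condition needs >= 2 samples")

  nonzero <- rowSums(counts) > 0
  n_allzero <- sum(!nonzero)
  m <- counts[nonzero, , drop = FALSE]
  sf <- size_factors(m)
  norm <- sweep(m, 2, sf, "/")

  i_ref <- condition == ref_level
  i_alt <- condition == alt_level
  q_ref <- rowMeans(norm[, i_ref, drop = FALSE])
  q_alt <- rowMeans(norm[, i_alt, drop = FALSE])
  base_mean <- rowMeans(norm)

  # moment dispersion pooled within groups: Var(K/s) ~ q/s + alpha q^2
  v_ref <- apply(norm[, i_ref, drop = FALSE], 1, var)
  v_alt <- apply(norm[, i_alt, drop = FALSE], 1, var)
  v_pool <- ((n1 - 1) * v_ref + (n2 - 1) * v_alt) / (n1 + n2 - 2)
  q_pool <- (n1 * q_ref + n2 * q_alt) / (n1 + n2)
  mean_inv_s <- mean(1 / sf)
  alpha <- pmax((v_pool - q_pool * mean_inv_s) / q_pool^2, 1e-8)
  alpha[!is.finite(alpha)] <- 1e-8

  tested <- base_mean >= min_mean
  # half-a-normalized-count floor keeps the log defined when a group is empty
  floor_q <- 0.5 * mean_inv_s / max(n1, n2)
  qr <- pmax(q_ref, floor_q); qa <- pmax(q_alt, floor_q)
  log2fc <- log2(qa / qr)
  # delta method on log(q): Var(qhat_group) = q * mean(1/s)/n + alpha q^2 / n
  var_ref <- (qr * mean(1 / sf[i_ref])) / n1 + alpha * qr^2 / n1
  var_alt <- (qa * mean(1 / sf[i_alt])) / n2 + alpha * qa^2 / n2
  se_log <- sqrt(var_ref / qr^2 + var_alt / qa^2)
  se_log2 <- se_log / log(2)
  z <- log2fc / se_log2
  p <- 2 * pnorm(-abs(z))
  p[!tested] <- NA_real_
  fdr <- rep(NA_real_, length(p))
  fdr[tested] <- bh_adjust(p[tested])

  call <- rep("ns", length(p))
  call[tested & fdr < fdr_gate & log2fc > log2(fc_gate)] <- "up"
  call[tested & fdr < fdr_gate & log2fc < -log2(fc_gate)] <- "down"

  tab <- tibble::tibble(
    gene_id = rownames(m), base_mean = base_mean,
    mean_ref = q_ref, mean_alt = q_alt,
    log2fc = log2fc, se = se_log2, p = p, fdr = fdr,
    call = factor(call, levels = c("down", "ns", "up"))
  )
  # keep gene order of the input for the genes that survived
  tab <- tab[order(match(tab$gene_id, rownames(counts))), ]
  structure(list(
    table = tab, size_factors = setNames(sf, colnames(m)),
    n_all_zero = n_allzero, n_tested = sum(tested),
    ref_level = ref_level, alt_level = alt_level,
    fc_gate = fc_gate, fdr_gate = fdr_gate, min_mean = min_mean
  ), class = "lnc_de")
}

#' @export
tidy.lnc_de <- function(x, ...) x$table

#' @export
glance.lnc_de <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$table) + x$n_all_zero,
    n_all_zero = x$n_all_zero,
    n_tested = x$n_tested,
    n_up = sum(x$table$call == "up"),
    n_down = sum(x$table$call == "down"),
    fc_gate = x$fc_gate, fdr_gate = x$fdr_gate
  )
}

#' @export
print.lnc_de <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "NB Wald differential expression (%s vs %s)\n  %d genes, %d tested; %d up / %d down at FC > %.2g & FDR < %.2g\n",
    x$alt_level, x$ref_level, g$n_genes, g$n_tested, g$n_up, g$n_down,
    x$fc_gate, x$fdr_gate))
  invisible(x)
}

#' Genes differentially expressed only in a focal cohort
#'
#' Given per-cohort differential-expression results, returns genes called
#' (`up` or `down`) in the focal cohort and not called in any other cohort.
#'
#' @param de_tables Named list of `lnc_de` objects or tidy DE tables.
#' @param focal Name of the focal cohort in `de_tables`.
#' @return Character vector of exclusively differential gene ids.
#' @export
cross_cohort_exclusivity <- function(de_tables, focal) {
  if (length(de_tables) < 2L) stop_input(">= 2 cohorts required")
  if (!focal %in% names(de_tables)) stop_input("focal cohort '%s' absent", focal)
  tabs <- lapply(de_tables, function(x) if (inherits(x, "lnc_de")) x$table else x)
  called <- lapply(tabs, function(t) t$gene_id[t$call != "ns"])
  others <- unlist(called[setdiff(names(tabs), focal)], use.names = FALSE)
  setdiff(called[[focal]], others)
}
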