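#' Per-sample gene-set activity scores (GSVA-style rank random walk)
#'
#' Unsupervised single-sample scoring of gene sets against a continuous
#' expression matrix. Per gene, a Gaussian-kernel CDF is estimated across
#' samples (bandwidth `sd/4`, floored at 1e-6 for constant rows); per
#' sample, genes are ranked by their CDF value in decreasing order and given
#' the symmetric rank weight `|N/2 - r|^tau`. A weighted Kolmogorov-Smirnov
#' random walk then steps up by the normalized weight at set genes and down
#' by `1/(N - m)` elsewhere; the score is the maximum positive deviation
#' plus the maximum negative deviation of the walk (the "maxdiff" variant).
#'
#' Because the construction only uses per-gene CDF ranks, scores are
#' invariant to any monotone transform applied per gene across samples.
#'
#' @param expr Expression matrix on the `log2FPKM` scale (use
#'   [log2()] of FPKM + 1, or any roughly symmetric continuous scale).
#' @param sets Named list of gene-id vectors; sets with fewer than 2 genes
#'   mapped to `expr` rows are dropped with a warning.
#' @param tau Rank-weight exponent (default 1).
#' @return Score matrix, sets x samples, of class `matrix` with attribute
#'   `provenance = "computed"`.
#' @examples
#' m <- matrix(rnorm(40), 10, 4,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' gsva_scores(as_expression_matrix(2^m, "FPKM") |> (\(x) log2(x + 1))() |>
#'               as_expression_matrix("log2FPKM"),
#'             list(A = c("g1", "g2", "g3")))
#' @export
gsva_scores <- function(expr, sets, tau = 1) {
  assert_unit(expr, "log2FPKM")
  if (ncol(expr) < 3L) stop_input(">= 3 samples required for CDF estimation")
  mapped <- lapply(sets, intersect, y = rownames(expr))
  drop <- lengths(mapped) < 2L
  if (any(drop)) {
    warn(sprintf("gsva_scores: dropping %d set(s) with < 2 mapped genes", sum(drop)))
    mapped <- mapped[!drop]
  }
  if (length(mapped) == 0L) stop_input("no usable gene sets")

  n_gene <- nrow(expr); n_samp <- ncol(expr)
  # Gaussian-kernel CDF per gene across samples: z_ij = mean_k Phi((x_ij - x_ik)/h_i)
  bw <- pmax(apply(expr, 1, sd), 1e-6) / 4
  z <- matrix(0, n_gene, n_samp, dimnames = dimnames(expr))
  for (i in seq_len(n_gene)) {
    x <- expr[i, ]
    z[i, ] <- rowMeans(pnorm(outer(x, x, "-") / bw[i]))
  }

  set_idx <- lapply(mapped, match, table = rownames(expr))
  scores <- matrix(NA_real_, length(mapped), n_samp,
                   dimnames = list(names(mapped), colnames(expr)))
  for (j in seq_len(n_samp)) {
    ord <- order(z[, j], decreasing = TRUE) # gene indices, best first
    r <- seq_len(n_gene)                    # rank along the ordering
    w <- abs(n_gene / 2 - r)^tau
    for (s in seq_along(set_idx)) {
      step_is_set <- ord %in% set_idx[[s]]
      m <- length(set_idx[[s]])
      inc <- ifelse(step_is_set, w / sum(w[step_is_set]), -1 / (n_gene - m))
      v <- cumsum(inc)
      scores[s, j] <- max(0, max(v)) + min(0, min(v))
    }
  }
  attr(scores, "provenance") <- "computed"
  scores
}

#' Attach externally supplied per-sample signature scores
#'
#' Inner-joins a supplied sample x signature score table onto the cohort's
#' samples. Samples absent on either side are dropped with a message; an
#' overlap below 50% aborts, since that usually signals a sample-id scheme
#' mismatch.
#'
#' @param scores Matrix (samples x signatures) or tibble with a `sample_id`
#'   column.
#' @param sample_ids Character vector of cohort sample ids to align to.
#' @return Signature x sample matrix with attribute `provenance =
#'   "supplied"`.
#' @export
attach_supplied_scores <- function(scores, sample_ids) {
  if (is.data.frame(scores)) {
    ids <- scores$sample_id
    m <- as.matrix(scores[, setdiff(names(scores), "sample_id"), drop = FALSE])
    rownames(m) <- ids
  } else {
    m <- scores
  }
  common <- intersect(sample_ids, rownames(m))
  if (length(common) < 0.5 * length(sample_ids)) {
    stop_input("only %d/%d samples match the supplied score table (id scheme mismatch?)",
               length(common), length(sample_ids))
  }
  n_drop <- length(rownames(m)) - length(common)
  if (n_drop > 0) inform(sprintf("attach_supplied_scores: dropped %d unmatched sample(s)", n_drop))
  out <- t(m[common, , drop = FALSE])
  attr(out, "provenance") <- "supplied"
  out
}

#' Compare a score between high and low expression groups
#'
#' Median-dichotomizes an expression vector and compares the companion score
#' (a gene-set activity, signature track, cell fraction, or checkpoint
#' expression) between the two groups with a two-sided Wilcoxon rank-sum
#' test: exact enumeration when both groups have at most 10 samples,
#' otherwise the normal approximation with continuity and tie correction.
#'
#' @param expr Non-constant expression vector defining the split.
#' @param score Numeric vector to compare, aligned to `expr`.
#' @return One-row tibble: `p`, `median_high`, `median_low`, `n_high`,
#'   `n_low`, `direction` (`"higher_in_high"` / `"higher_in_low"` /
#'   `"none"`).
#' @export
compare_high_low <- function(expr, score) {
  if (length(expr) != length(score)) stop_input("expr and score must be aligned")
  grp <- dichotomize_median(expr)
  hi <- score[grp == "high"]; lo <- score[grp == "low"]
  if (length(unique(score)) < 2L) {
    warn("compare_high_low: constant score vector; p = 1")
    p <- 1
  } else {
    exact <- length(hi) <= 10 && length(lo) <= 10
    p <- suppressWarnings(
      wilcox.test(hi, lo, exact = exact, correct = TRUE)$p.value)
  }
  mh <- median(hi); ml <- median(lo)
  tibble::tibble(
    p = p, median_high = mh, median_low = ml,
    n_high = length(hi), n_low = length(lo),
    direction = dplyr::case_when(mh > ml ~ "higher_in_high",
                                 mh < ml ~ "higher_in_low",
                                 TRUE ~ "none"))
}
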