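#' Immune-cell fraction estimation by non-negative least squares
#'
#' Per sample, solves `min || S f - m ||_2` subject to `f >= 0` over the
#' signature genes shared between the mixture and the signature matrix, then
#' renormalizes `f` to sum to one. Runs on linear-scale expression (FPKM or
#' counts-per-scale, never log). Deterministic, and scale-invariant in the
#' mixture after renormalization.
#'
#' @param expr Mixture expression matrix (linear scale), genes x samples.
#' @param signature Signature matrix, signature-gene x cell-type; must be
#'   full column rank and at least 50% of its genes must be present in
#'   `expr`.
#' @return Object of class `cell_fractions`: a sample x cell-type matrix of
#'   proportions with attribute `residual` (per-sample relative residual
#'   norm `||S f - m|| / ||m||`). `tidy()` returns it in long form.
#' @examples
#' S <- matrix(c(10, 0, 0, 10), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("A", "B")))
#' m <- matrix(c(5, 5), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' deconvolve(m, S)
#' @export
deconvolve <- function(expr, signature) {
  assert_matrix(signature, "signature")
  if (is.null(dim(expr))) stop_input("`expr` must be a matrix")
  common <- intersect(rownames(signature), rownames(expr))
  if (length(common) < 0.5 * nrow(signature)) {
    stop_input("only %d/%d signature genes present in the mixture",
               length(common), nrow(signature))
  }
  n_missing <- nrow(signature) - length(common)
  if (n_missing > 0) {
    inform(sprintf("deconvolve: %d signature genes missing from the mixture", n_missing))
  }
  S <- signature[common, , drop = FALSE]
  if (qr(S)$rank < ncol(S)) stop_input("signature matrix is rank-deficient on the shared genes")
  if (ncol(S) < 2L) stop_input(">= 2 cell types required")
  M <- expr[common, , drop = FALSE]
  k <- ncol(S)
  frac <- matrix(0, ncol(M), k, dimnames = list(colnames(M), colnames(S)))
  resid <- numeric(ncol(M))
  for (j in seq_len(ncol(M))) {
    m <- M[, j]
    sol <- pracma::lsqnonneg(S, m)
    f <- sol$x
    s <- sum(f)
    frac[j, ] <- if (s > 0) f / s else rep(1 / k, k)
    mnorm <- sqrt(sum(m^2))
    resid[j] <- if (mnorm > 0) sqrt(sum((S %*% f - m)^2)) / mnorm else 0
  }
  structure(frac, residual = setNames(resid, colnames(M)), class = c("cell_fractions", "matrix"))
}

#' @export
tidy.cell_fractions <- function(x, ...) {
  res <- attr(x, "residual")
  out <- tibble::as_tibble(unclass_fractions(x), rownames = "sample_id")
  out <- tidyr::pivot_longer(out, -"sample_id",
                             names_to = "cell_type", values_to = "fraction")
  dplyr::left_join(out, tibble::tibble(sample_id = names(res), residual = res),
                   by = "sample_id")
}

unclass_fractions <- function(x) {
  attr(x, "residual") <- NULL
  class(x) <- "matrix"
  m <- matrix(as.numeric(x), nrow(x), ncol(x), dimnames = dimnames(x))
  m
}

#' Correlate lncRNAs with estimated immune-cell fractions
#'
#' Delegates to [correlate_tracks()] with the cell-type fraction columns as
#' tracks, and summarizes per cell type how many lncRNAs are significantly
#' positively and negatively correlated.
#'
#' @param expr Expression matrix on the `log2FPKM` scale.
#' @param lnc_ids lncRNA row ids.
#' @param fractions A `cell_fractions` matrix from [deconvolve()] (or any
#'   sample x cell-type matrix).
#' @param rs_gate,fdr_gate Significance gates.
#' @return List with `records` (the [correlate_tracks()] tibble with
#'   `track` renamed `cell_type`) and `summary` (per-cell-type counts of
#'   significant positive/negative lncRNAs).
#' @export
cell_correlations <- function(expr, lnc_ids, fractions, rs_gate = 0.3, fdr_gate = 0.05) {
  m <- if (inherits(fractions, "cell_fractions")) unclass_fractions(fractions) else fractions
  rec <- correlate_tracks(expr, lnc_ids, t(m), rs_gate = rs_gate, fdr_gate = fdr_gate)
  rec <- dplyr::rename(rec, cell_type = "track")
  summ <- dplyr::summarise(
    dplyr::group_by(rec, .data$cell_type),
    n_positive = sum(.data$significant & .data$direction == "positive", na.rm = TRUE),
    n_negative = sum(.data$significant & .data$direction == "negative", na.rm = TRUE),
    .groups = "drop")
  list(records = rec, summary = summ)
}
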