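#' Spearman correlation with a t-approximation p-value
#'
#' Average-rank ties; `Rs` is the Pearson correlation of the ranks; the
#' two-sided p-value comes from `t = Rs * sqrt((n - 2) / (1 - Rs^2))` on
#' `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return One-row tibble: `rs`, `p`, `n`.
#' @examples
#' spearman(c(1, 2, 3, 4), c(10, 20, 30, 40))
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop_input("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop_input(">= 4 complete observations required")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(tibble::tibble(rs = NA_real_, p = NA_real_, n = n))
  }
  rs <- cor(rank(x), rank(y))
  p <- spearman_p(rs, n)
  tibble::tibble(rs = rs, p = p, n = n)
}

spearman_p <- function(rs, n) {
  rs_c <- pmin(pmax(rs, -1 + 1e-15), 1 - 1e-15)
  tt <- rs_c * sqrt((n - 2) / (1 - rs_c^2))
  2 * pt(-abs(tt), df = n - 2)
}

# all-pairs Spearman between rows of X and rows of Y (same sample columns);
# returns list(rs, p) of dim nrow(X) x nrow(Y); constant rows give NA
spearman_matrix <- function(X, Y) {
  n <- ncol(X)
  rx <- t(apply(X, 1, rank))
  ry <- t(apply(Y, 1, rank))
  const_x <- apply(X, 1, function(v) length(unique(v)) < 2L)
  const_y <- apply(Y, 1, function(v) length(unique(v)) < 2L)
  rs <- suppressWarnings(cor(t(rx), t(ry)))
  rs[const_x, ] <- NA_real_
  rs[, const_y] <- NA_real_
  p <- spearman_p(rs, n)
  p[is.na(rs)] <- NA_real_
  list(rs = rs, p = p)
}

#' Correlation partner sets for lncRNAs
#'
#' Computes every lncRNA x candidate-gene Spearman correlation across
#' samples, adjusts p-values per lncRNA (Benjamini-Hochberg over that
#' lncRNA's candidate family), and flags significant partners by the double
#' gate `|Rs| > rs_gate` and `FDR < fdr_gate`. Constant rows yield an
#' undefined-correlation sentinel (`NA`) and are excluded from the BH
#' family.
#'
#' @param expr Expression matrix on the `log2FPKM` scale.
#' @param lnc_ids lncRNA row ids.
#' @param candidate_ids Candidate partner row ids (disjoint from
#'   `lnc_ids`).
#' @param rs_gate,fdr_gate Significance gates (defaults 0.3 and 0.05).
#' @return Tibble: `lnc`, `partner`, `rs`, `p`, `fdr`, `significant`;
#'   attribute `fdr_family = "per_lncRNA"`.
#' @export
partner_sets <- function(expr, lnc_ids, candidate_ids,
                         rs_gate = 0.3, fdr_gate = 0.05) {
  assert_unit(expr, "log2FPKM")
  if (length(candidate_ids) == 0L) stop_input("empty candidate universe")
  if (length(intersect(lnc_ids, candidate_ids)) > 0L) {
    stop_input("lnc_ids and candidate_ids must be disjoint")
  }
  bad <- setdiff(c(lnc_ids, candidate_ids), rownames(expr))
  if (length(bad) > 0) stop_input("%d requested ids absent from the matrix", length(bad))
  sm <- spearman_matrix(expr[lnc_ids, , drop = FALSE],
                        expr[candidate_ids, , drop = FALSE])
  out <- tibble::tibble(
    lnc = rep(lnc_ids, times = length(candidate_ids)),
    partner = rep(candidate_ids, each = length(lnc_ids)),
    rs = as.vector(sm$rs),
    p = as.vector(sm$p)
  )
  out <- dplyr::group_by(out, .data$lnc)
  out <- dplyr::mutate(out, fdr = bh_adjust(.data$p))
  out <- dplyr::ungroup(out)
  out$significant <- !is.na(out$rs) & abs(out$rs) > rs_gate & out$fdr < fdr_gate
  attr(out, "fdr_family") <- "per_lncRNA"
  out
}

#' Correlate lncRNAs with per-sample numeric tracks
#'
#' Spearman correlation of each lncRNA against each track (immunogenomic
#' signature scores, immune-cell fractions, or checkpoint-gene expression
#' rows), over the shared samples. BH adjustment is across all pairs in the
#' call; the significance gate is `|Rs| > rs_gate` and `FDR < fdr_gate`.
#'
#' @param expr Expression matrix on the `log2FPKM` scale.
#' @param lnc_ids lncRNA row ids.
#' @param tracks Numeric matrix, track x sample; column names must overlap
#'   at least 50% of `expr` samples.
#' @param rs_gate,fdr_gate Significance gates.
#' @return Tibble: `lnc`, `track`, `rs`, `p`, `fdr`, `significant`,
#'   `direction` (`"positive"`/`"negative"`); attribute
#'   `fdr_family = "per_call"`.
#' @export
correlate_tracks <- function(expr, lnc_ids, tracks, rs_gate = 0.3, fdr_gate = 0.05) {
  assert_unit(expr, "log2FPKM")
  common <- intersect(colnames(expr), colnames(tracks))
  if (length(common) < 0.5 * ncol(tracks)) {
    stop_input("only %d/%d track samples align with expression", length(common), ncol(tracks))
  }
  sm <- spearman_matrix(expr[lnc_ids, common, drop = FALSE],
                        tracks[, common, drop = FALSE][seq_len(nrow(tracks)), , drop = FALSE])
  out <- tibble::tibble(
    lnc = rep(lnc_ids, times = nrow(tracks)),
    track = rep(rownames(tracks), each = length(lnc_ids)),
    rs = as.vector(sm$rs),
    p = as.vector(sm$p)
  )
  out$fdr <- bh_adjust(out$p)
  out$significant <- !is.na(out$rs) & abs(out$rs) > rs_gate & out$fdr < fdr_gate
  out$direction <- ifelse(is.na(out$rs), NA_character_,
                          ifelse(out$rs > 0, "positive", "negative"))
  attr(out, "fdr_family") <- "per_call"
  out
}

#' Track-exclusivity of significant lncRNAs
#'
#' From a [correlate_tracks()] result, lncRNAs significant for exactly one
#' track are flagged exclusive for it.
#'
#' @param track_cor Tibble from [correlate_tracks()].
#' @return Tibble of significant records with an added `exclusive` flag.
#' @export
track_exclusivity <- function(track_cor) {
  sig <- dplyr::filter(track_cor, .data$significant)
  counts <- dplyr::count(sig, .data$lnc, name = "n_tracks")
  dplyr::mutate(dplyr::left_join(sig, counts, by = "lnc"),
                exclusive = .data$n_tracks == 1L)
}
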