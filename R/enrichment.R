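#' Build the 2x2 table for one lncRNA-feature enrichment test
#'
#' `a` = partners inside the feature set, `b` = partners outside, `c` =
#' feature genes that are not partners, `d` = the rest of the universe.
#'
#' @param feature_genes Gene ids of the feature set (subset of `universe`).
#' @param partners Significant partner gene ids (subset of `universe`).
#' @param universe All candidate genes entering the correlation screen.
#' @return Named integer vector `c(a, b, c, d)`.
#' @examples
#' build_contingency(letters[1:5], letters[1:5], letters[1:10])
#' @export
build_contingency <- function(feature_genes, partners, universe) {
  if (length(universe) == 0L) stop_input("empty universe")
  feature_genes <- intersect(feature_genes, universe)
  partners <- intersect(partners, universe)
  a <- length(intersect(partners, feature_genes))
  b <- length(partners) - a
  cc <- length(feature_genes) - a
  d <- length(universe) - a - b - cc
  c(a = a, b = b, c = cc, d = d)
}

#' One-sided exact enrichment test on a 2x2 table
#'
#' The p-value is the upper hypergeometric tail `P(X >= a)` with `a + c`
#' feature genes, `b + d` non-feature genes and `a + b` draws — identical
#' for `kind = "fisher"` (one-sided Fisher's exact test in the enrichment
#' direction) and `kind = "hypergeometric"`; both names are exposed because
#' hallmark and immune-process screens are conventionally described with
#' either. The odds ratio is `(a d)/(b c)`, with the Haldane-Anscombe +0.5
#' applied to all cells when any cell is zero (display only; never inside
#' the tail probability).
#'
#' @param tab Named vector or list with elements `a`, `b`, `c`, `d`.
#' @param kind `"fisher"` or `"hypergeometric"`.
#' @return One-row tibble: `or`, `p`, `test`.
#' @examples
#' enrichment_test(c(a = 5, b = 0, c = 0, d = 5)) # p = 1/choose(10, 5)
#' @export
enrichment_test <- function(tab, kind = c("fisher", "hypergeometric")) {
  kind <- match.arg(kind)
  a <- tab[["a"]]; b <- tab[["b"]]; cc <- tab[["c"]]; d <- tab[["d"]]
  if (any(c(a, b, cc, d) < 0)) stop_input("negative cell counts")
  or <- if (any(c(a, b, cc, d) == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    (a * d) / (b * cc)
  }
  p <- phyper(a - 1, a + cc, b + d, a + b, lower.tail = FALSE)
  tibble::tibble(or = or, p = p, test = kind)
}

#' Enrichment of lncRNA correlation partners in gene-set collections
#'
#' For every lncRNA in the partner table and every set of every collection,
#' builds the 2x2 partner/feature table over the shared universe, runs the
#' one-sided exact test, BH-adjusts per collection (across all lncRNA x set
#' pairs of that collection), and flags `enriched` when `OR > or_gate` and
#' `FDR < fdr_gate`.
#'
#' @param partner_tbl Tibble from [partner_sets()].
#' @param collections Named list of gene-set collections (each a named list
#'   of gene-id vectors), e.g. `list(hallmark = ..., immune_process = ...)`.
#' @param universe Candidate-gene universe used for the partner screen
#'   (defaults to the distinct partners column of `partner_tbl`).
#' @param test `"fisher"` or `"hypergeometric"`; a single value or one per
#'   collection (recycled).
#' @param or_gate,fdr_gate Enrichment gates (defaults 1 and 0.05).
#' @return Tibble: `lnc`, `collection`, `feature`, `a`, `b`, `c`, `d`,
#'   `or`, `p`, `fdr`, `enriched`, `test`; attribute
#'   `fdr_family = "per_collection"`.
#' @export
enrich_all <- function(partner_tbl, collections, universe = NULL,
                       test = "fisher", or_gate = 1, fdr_gate = 0.05) {
  if (length(collections) == 0L) stop_input("no collections supplied")
  if (is.null(names(collections))) stop_input("collections must be named")
  universe <- universe %||% unique(partner_tbl$partner)
  test <- rep_len(test, length(collections))
  sig <- dplyr::filter(partner_tbl, .data$significant)
  sig_by_lnc <- split(sig$partner, factor(sig$lnc, levels = unique(partner_tbl$lnc)))
  lncs <- names(sig_by_lnc)
  n_univ <- length(universe)

  out <- purrr::imap_dfr(collections, function(sets, coll_name) {
    sets <- restrict_sets(sets, universe)
    k <- match(coll_name, names(collections))
    # membership matrix: universe x sets
    member <- vapply(sets, function(g) universe %in% g, logical(n_univ))
    set_sizes <- colSums(member)
    rows <- purrr::map_dfr(lncs, function(l) {
      partners <- intersect(sig_by_lnc[[l]], universe)
      n_part <- length(partners)
      a <- if (n_part == 0L) integer(ncol(member)) else
        colSums(member[universe %in% partners, , drop = FALSE])
      b <- n_part - a
      cc <- set_sizes - a
      d <- n_univ - n_part - cc
      zero <- a == 0 | b == 0 | cc == 0 | d == 0
      or <- ifelse(zero,
                   ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5)),
                   (a * d) / (b * cc))
      p <- phyper(a - 1, a + cc, b + d, a + b, lower.tail = FALSE)
      tibble::tibble(lnc = l, collection = coll_name, feature = names(sets),
                     a = as.integer(a), b = as.integer(b),
                     c = as.integer(cc), d = as.integer(d),
                     or = or, p = p, test = test[k])
    })
    rows$fdr <- bh_adjust(rows$p)
    rows
  })
  out$enriched <- out$or > or_gate & out$fdr < fdr_gate
  attr(out, "fdr_family") <- "per_collection"
  out
}

#' Gene-level mediation edges behind enriched lncRNA-feature pairs
#'
#' For each enriched pair, the feature genes that are significant
#' correlation partners of that lncRNA, ranked by `|Rs|`, keeping the top
#' `top_k`. These are the candidate genes through which the lncRNA may
#' regulate the feature.
#'
#' @param partner_tbl Tibble from [partner_sets()].
#' @param collections Named list of gene-set collections.
#' @param enriched_tbl Tibble from [enrich_all()] (only rows with
#'   `enriched = TRUE` are used).
#' @param top_k Maximum edges kept per enriched pair (default 5).
#' @return Tibble: `lnc`, `collection`, `feature`, `gene_id`, `rs`, `sign`.
#' @export
mediation_edges <- function(partner_tbl, collections, enriched_tbl, top_k = 5) {
  sig <- dplyr::filter(partner_tbl, .data$significant)
  enr <- dplyr::filter(enriched_tbl, .data$enriched)
  if (nrow(enr) == 0L) {
    return(tibble::tibble(lnc = character(), collection = character(),
                          feature = character(), gene_id = character(),
                          rs = numeric(), sign = numeric()))
  }
  purrr::pmap_dfr(enr[, c("lnc", "collection", "feature")], function(lnc, collection, feature) {
    genes <- collections[[collection]][[feature]]
    hits <- sig[sig$lnc == lnc & sig$partner %in% genes, ]
    hits <- hits[order(-abs(hits$rs)), ]
    hits <- head(hits, top_k)
    tibble::tibble(lnc = lnc, collection = collection, feature = feature,
                   gene_id = hits$partner, rs = hits$rs, sign = sign(hits$rs))
  })
}
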