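# ggplot2 views of the main result types; all take the fitted object /
# record tibbles the stages already produce

#' @describeIn differential_expression Volcano plot of the per-gene table.
#' @param object,x An `lnc_de` object.
#' @param ... Unused.
#' @export
autoplot.lnc_de <- function(object, ...) {
  tab <- dplyr::filter(tidy(object), !is.na(.data$p))
  ggplot2::ggplot(tab, ggplot2::aes(.data$log2fc, -log10(pmax(.data$p, 1e-300)),
                                    colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(object$fc_gate), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(down = "#3366aa", ns = "grey70", up = "#aa3333")) +
    ggplot2::labs(x = "log2 fold change (tumor vs normal)", y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves for a median-split gene
#'
#' @param fpkm FPKM matrix.
#' @param gene Gene id (row of `fpkm`).
#' @param clinical Clinical tibble with `sample_id` and endpoint columns.
#' @param endpoint `"os"` or `"dfs"`.
#' @return A ggplot: step survival curves for the high and low groups with
#'   the log-rank p in the subtitle.
#' @export
plot_km <- function(fpkm, gene, clinical, endpoint = "os") {
  assert_unit(fpkm, "FPKM")
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  cl <- clinical[!is.na(clinical[[tcol]]) & clinical$sample_id %in% colnames(fpkm), ]
  x <- log2(fpkm[gene, cl$sample_id] + 1)
  grp <- dichotomize_median(x)
  km <- km_estimate(cl[[tcol]], cl[[ecol]], grp)
  lr <- logrank_test(grp, cl[[tcol]], cl[[ecol]])
  base <- tibble::tibble(group = levels(grp), time = 0, surv = 1)
  ggplot2::ggplot(dplyr::bind_rows(base, km[, c("group", "time", "surv")]),
                  ggplot2::aes(.data$time, .data$surv, colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(title = gene, subtitle = sprintf("log-rank p = %.3g", lr$p),
                  x = "time", y = "survival probability", colour = "expression") +
    ggplot2::theme_minimal()
}

#' Bubble plot of lncRNA-feature enrichment
#'
#' @param enrichment Tibble from [enrich_all()].
#' @param collection Collection to show.
#' @param max_features Show at most this many features (by enriched-lncRNA
#'   count).
#' @return A ggplot: features vs enriched-lncRNA count, bubble size
#'   `-log10 FDR` of the best pair.
#' @export
plot_enrichment <- function(enrichment, collection = "hallmark", max_features = 30) {
  enr <- dplyr::filter(enrichment, .data$collection == !!collection, .data$enriched)
  if (nrow(enr) == 0L) stop_input("no enriched pairs in collection '%s'", collection)
  top <- dplyr::summarise(dplyr::group_by(enr, .data$feature),
                          n_lnc = dplyr::n_distinct(.data$lnc),
                          best = -log10(pmax(min(.data$fdr), 1e-300)),
                          .groups = "drop")
  top <- head(dplyr::arrange(top, dplyr::desc(.data$n_lnc)), max_features)
  ggplot2::ggplot(top, ggplot2::aes(.data$n_lnc,
                                    stats::reorder(.data$feature, .data$n_lnc),
                                    size = .data$best)) +
    ggplot2::geom_point(colour = "#aa3333", alpha = 0.8) +
    ggplot2::labs(x = "enriched lncRNAs", y = NULL, size = "-log10 FDR (best pair)") +
    ggplot2::theme_minimal()
}

#' Diamond-grid view of lncRNA-immune-cell correlations
#'
#' @param cell_cor `records` tibble from [cell_correlations()].
#' @param max_lnc Show at most this many lncRNAs (by significant-cell
#'   count).
#' @return A ggplot: lncRNA x cell type grid, colour = Spearman Rs, size =
#'   `-log10 FDR`, significant records only.
#' @export
plot_cell_grid <- function(cell_cor, max_lnc = 25) {
  sig <- dplyr::filter(cell_cor, .data$significant)
  if (nrow(sig) == 0L) stop_input("no significant lncRNA-cell correlations")
  keep <- head(names(sort(table(sig$lnc), decreasing = TRUE)), max_lnc)
  sig <- dplyr::filter(sig, .data$lnc %in% keep)
  ggplot2::ggplot(sig, ggplot2::aes(.data$cell_type, .data$lnc,
                                    colour = .data$rs,
                                    size = -log10(pmax(.data$fdr, 1e-300)))) +
    ggplot2::geom_point(shape = 18) +
    ggplot2::scale_colour_gradient2(low = "#3366aa", mid = "white", high = "#aa3333") +
    ggplot2::labs(x = NULL, y = NULL, colour = "Spearman Rs", size = "-log10 FDR") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
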