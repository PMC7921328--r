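#' The 22 LM22 leukocyte cell types
#'
#' Returns the ordered list of cell-type names in the LM22 leukocyte signature
#' used for bulk expression deconvolution: 22 functionally defined immune cell
#' populations, from naive B cells through granulocytes.
#'
#' @return Character vector of length 22, starting `"B cells naive"` and
#'   ending `"Neutrophils"`.
#' @examples
#' lm22_cell_types()
#' @export
lm22_cell_types <- function() {
  c(
    "B cells naive",
    "B cells memory",
    "Plasma cells",
    "T cells CD8",
    "T cells CD4 naive",
    "T cells CD4 memory resting",
    "T cells CD4 memory activated",
    "T cells follicular helper",
    "T cells regulatory (Tregs)",
    "T cells gamma delta",
    "NK cells resting",
    "NK cells activated",
    "Monocytes",
    "Macrophages M0",
    "Macrophages M1",
    "Macrophages M2",
    "Dendritic cells resting",
    "Dendritic cells activated",
    "Mast cells resting",
    "Mast cells activated",
    "Eosinophils",
    "Neutrophils"
  )
}

#' Default immune checkpoint gene list
#'
#' Inhibitory immune-regulatory genes targeted by checkpoint-blockade therapy.
#' PDCD1 encodes PD-1 and CD274 encodes PD-L1.
#'
#' @return Character vector of HGNC symbols.
#' @export
checkpoint_genes <- function() {
  c("PDCD1", "CD274", "CTLA4", "TIGIT")
}
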