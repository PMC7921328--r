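# plain-text serialization: TSV for matrices/tables, standard GMT for gene sets

#' Write a named numeric matrix as TSV
#'
#' Rows become a leading id column; the header row carries column names.
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output file path.
#' @param id_col Name for the leading row-id column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  assert_matrix(m, "m", allow_negative = TRUE)
  df <- tibble::as_tibble(m, rownames = id_col)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a TSV written by [write_matrix_tsv()] back into a matrix
#'
#' @param path File path; first column is taken as row names.
#' @param unit Optional expression unit tag to attach
#'   (`"counts"`, `"FPKM"`, `"log2FPKM"`).
#' @return Numeric matrix (with `expr_unit` attribute when `unit` is given).
#' @export
read_matrix_tsv <- function(path, unit = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  if (!is.null(unit)) m <- expression_matrix(m, unit)
  m
}

#' Read a GMT gene-set file
#'
#' Standard MSigDB dialect: one set per line, `name TAB description TAB
#' gene1 TAB gene2 ...`.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) stop_input("malformed GMT line (need name, description, >=1 gene)")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop_input("duplicate gene-set names in %s", path)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict a gene-set collection to an annotation universe
#'
#' Drops ids absent from `universe` and then sets left with fewer than
#' `min_size` genes, with a message describing what was dropped.
#'
#' @param sets Named list of gene-id vectors.
#' @param universe Character vector of admissible gene ids.
#' @param min_size Minimum mapped set size to keep.
#' @return Filtered named list.
#' @export
restrict_sets <- function(sets, universe, min_size = 2L) {
  mapped <- lapply(sets, intersect, y = universe)
  n_drop <- sum(lengths(sets) - lengths(mapped))
  if (n_drop > 0) inform(sprintf("restrict_sets: dropped %d gene ids outside the universe", n_drop))
  keep <- lengths(mapped) >= min_size
  if (any(!keep)) {
    inform(sprintf("restrict_sets: dropped %d sets with < %d mapped genes", sum(!keep), min_size))
  }
  if (!any(keep)) stop_input("no usable gene sets after restriction to the universe")
  mapped[keep]
}
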