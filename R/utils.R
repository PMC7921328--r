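# internal helpers shared across stages

`%||%` <- rlang::`%||%`

stop_input <- function(msg, ...) rlang::abort(sprintf(msg, ...), class = "lncimmune_error")

# single-scalar validators; used at every user-facing boundary
assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_input("`%s` must be a single finite number in [%s, %s]", name, lower, upper)
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x != round(x)) {
    stop_input("`%s` must be a single integer >= %d", name, lower)
  }
  invisible(as.integer(x))
}

assert_matrix <- function(x, name, allow_negative = FALSE) {
  if (!is.matrix(x) || !is.numeric(x)) stop_input("`%s` must be a numeric matrix", name)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop_input("`%s` must have row (gene) and column (sample) names", name)
  }
  if (!allow_negative && any(x < 0, na.rm = TRUE)) {
    stop_input("`%s` must not contain negative entries", name)
  }
  invisible(x)
}

# expression matrices carry their unit as an attribute so stages can refuse
# inputs on the wrong scale
expression_matrix <- function(values, unit = c("counts", "FPKM", "log2FPKM")) {
  unit <- match.arg(unit)
  assert_matrix(values, "values", allow_negative = unit == "log2FPKM")
  structure(values, expr_unit = unit)
}

expr_unit <- function(x) attr(x, "expr_unit") %||% "counts"

assert_unit <- function(x, unit, name = deparse(substitute(x))) {
  if (!identical(expr_unit(x), unit)) {
    stop_input("`%s` must be on the %s scale (got %s)", name, unit, expr_unit(x))
  }
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over [stats::p.adjust()] that tolerates `NA`s and empty input;
#' kept as a named seam so every stage adjusts through the same door and the
#' test suite can compare it against a brute-force reference.
#'
#' @param p Numeric vector of p-values.
#' @return Numeric vector of BH-adjusted p-values, same length as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

# log2(FPKM + 1); the scale used for correlations and gene-set scoring
log2_fpkm <- function(fpkm) {
  assert_unit(fpkm, "FPKM")
  expression_matrix(log2(fpkm + 1), "log2FPKM")
}
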