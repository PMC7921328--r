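#' Univariate Cox proportional-hazards regression
#'
#' Fits a single-covariate Cox model by partial likelihood with the Efron
#' approximation for tied event times. A monotone-likelihood fit (groups
#' perfectly separated in risk) is flagged `converged = FALSE` with an
#' infinite hazard-ratio sentinel so callers can exclude it from ranking.
#'
#' @param expr Numeric covariate vector (one value per subject).
#' @param time Follow-up times (> 0).
#' @param event Event indicator (1 = event, 0 = censored).
#' @return One-row tibble: `beta`, `se`, `z`, `p`, `hr`, `n`, `n_event`,
#'   `converged`.
#' @export
cox_univariate <- function(expr, time, event) {
  ok <- is.finite(expr) & is.finite(time) & !is.na(event)
  expr <- expr[ok]; time <- time[ok]; event <- as.integer(event[ok])
  if (any(time <= 0)) stop_input("survival times must be positive")
  if (!all(event %in% c(0L, 1L))) stop_input("event must be binary 0/1")
  if (sum(event) < 1L) stop_input("at least one event required")
  fit <- NULL
  diverged <- FALSE
  withCallingHandlers(
    fit <- survival::coxph(survival::Surv(time, event) ~ expr,
                           ties = "efron",
                           control = survival::coxph.control(eps = 1e-10, iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w))) diverged <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  beta <- unname(fit$coefficients)
  se <- sqrt(unname(diag(fit$var)))
  if (diverged || !is.finite(beta) || se > 1e3) {
    return(tibble::tibble(beta = sign(beta) * Inf, se = Inf, z = NA_real_,
                          p = NA_real_, hr = if (beta > 0) Inf else 0,
                          n = length(time), n_event = sum(event),
                          converged = FALSE))
  }
  z <- beta / se
  tibble::tibble(beta = beta, se = se, z = z, p = 2 * pnorm(-abs(z)),
                 hr = exp(beta), n = length(time), n_event = sum(event),
                 converged = TRUE)
}

#' Median dichotomization of an expression vector
#'
#' Values above the median are `"high"`; values at or below the median are
#' `"low"` (ties at the median go to the low group, a deterministic rule that
#' keeps both groups non-empty for any non-constant vector).
#'
#' @param expr Numeric vector, length >= 2, not constant.
#' @return Factor of `"low"`/`"high"` labels, same length as `expr`.
#' @examples
#' dichotomize_median(c(1, 2, 2, 3))
#' @export
dichotomize_median <- function(expr) {
  if (length(expr) < 2L) stop_input(">= 2 samples required")
  if (length(unique(expr[is.finite(expr)])) < 2L) {
    stop_input("constant expression vector: no median split possible")
  }
  med <- median(expr, na.rm = TRUE)
  factor(ifelse(expr > med, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator `S(t) = prod(1 - d_i / n_i)` over event times up
#' to `t`, computed with [survival::survfit()].
#'
#' @param time Follow-up times.
#' @param event Event indicator (1/0).
#' @param group Optional grouping factor; one curve per level.
#' @return Tibble with `group` (if given), `time`, `n_risk`, `n_event`,
#'   `surv`.
#' @export
km_estimate <- function(time, event, group = NULL) {
  if (any(time <= 0)) stop_input("survival times must be positive")
  event <- as.integer(event)
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                   n_event = fit$n.event, surv = fit$surv)
  } else {
    fit <- survival::survfit(survival::Surv(time, event) ~ group)
    strata <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
    tibble::tibble(group = strata, time = fit$time, n_risk = fit$n.risk,
                   n_event = fit$n.event, surv = fit$surv)
  }
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic, chi-squared with 1 degree of freedom, via
#' [survival::survdiff()].
#'
#' @param group Two-level grouping vector.
#' @param time Follow-up times.
#' @param event Event indicator.
#' @return One-row tibble: `chisq`, `p`.
#' @export
logrank_test <- function(group, time, event) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) != 2L) stop_input("exactly two non-empty groups required")
  fit <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ group)
  tibble::tibble(chisq = fit$chisq, p = stats::pchisq(fit$chisq, df = 1, lower.tail = FALSE))
}

#' Prognostic screen of differential lncRNAs
#'
#' For each candidate gene with median FPKM above `min_expr`, fits a
#' univariate Cox model on log2(FPKM + 1), labels it `good` (HR < 1,
#' p < `p_gate`), `bad` (HR > 1, p < `p_gate`) or `ns`, and reports the
#' companion median-split log-rank p-value. Raw Cox p drives the label; a
#' BH-adjusted column is also emitted. Run separately per endpoint.
#'
#' @param fpkm FPKM matrix.
#' @param genes Candidate gene ids (rows of `fpkm`), e.g. differential
#'   lncRNAs.
#' @param clinical Tibble with `sample_id` plus `<endpoint>_time` /
#'   `<endpoint>_event` columns (e.g. `os_time`, `os_event`).
#' @param endpoint Endpoint prefix, `"os"` or `"dfs"`.
#' @param min_expr Median-FPKM expression filter (default 1).
#' @param p_gate Significance gate on the raw Cox p-value.
#' @return Object of class `lnc_prognosis`; `tidy()` gives the per-gene
#'   table ranked by p (`gene_id`, `hr`, `beta`, `se`, `p`, `q`,
#'   `logrank_p`, `label`), `glance()` counts per label.
#' @export
prognostic_screen <- function(fpkm, genes, clinical, endpoint = "os",
                              min_expr = 1, p_gate = 0.05) {
  assert_unit(fpkm, "FPKM")
  missing <- setdiff(genes, rownames(fpkm))
  if (length(missing) > 0) stop_input("%d screened genes absent from the matrix", length(missing))
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  if (!all(c(tcol, ecol) %in% names(clinical))) {
    stop_input("clinical table lacks %s/%s", tcol, ecol)
  }
  cl <- clinical[!is.na(clinical[[tcol]]) & !is.na(clinical[[ecol]]), ]
  cl <- cl[cl$sample_id %in% colnames(fpkm), ]
  m <- fpkm[, cl$sample_id, drop = FALSE]

  keep <- genes[apply(m[genes, , drop = FALSE], 1, median) > min_expr]
  if (length(keep) == 0L) {
    warn("prognostic_screen: no genes pass the expression filter")
    tab <- tibble::tibble(gene_id = character(), hr = numeric(), beta = numeric(),
                          se = numeric(), p = numeric(), q = numeric(),
                          logrank_p = numeric(), label = character())
    return(structure(list(table = tab, endpoint = endpoint, min_expr = min_expr,
                          p_gate = p_gate, n_candidates = length(genes)),
                     class = "lnc_prognosis"))
  }
  rows <- purrr::map_dfr(keep, function(g) {
    x <- log2(m[g, ] + 1)
    cx <- cox_univariate(x, cl[[tcol]], cl[[ecol]])
    lr <- tryCatch({
      grp <- dichotomize_median(x)
      logrank_test(grp, cl[[tcol]], cl[[ecol]])$p
    }, error = function(e) NA_real_)
    tibble::tibble(gene_id = g, hr = cx$hr, beta = cx$beta, se = cx$se,
                   p = cx$p, logrank_p = lr, converged = cx$converged)
  })
  rows$q <- bh_adjust(rows$p)
  rows$label <- dplyr::case_when(
    !rows$converged | is.na(rows$p) ~ "unstable",
    rows$p < p_gate & rows$hr < 1 ~ "good",
    rows$p < p_gate & rows$hr > 1 ~ "bad",
    TRUE ~ "ns"
  )
  tab <- dplyr::arrange(
    dplyr::select(rows, "gene_id", "hr", "beta", "se", "p", "q", "logrank_p", "label"),
    .data$p)
  structure(list(table = tab, endpoint = endpoint, min_expr = min_expr,
                 p_gate = p_gate, n_candidates = length(genes)),
            class = "lnc_prognosis")
}

#' @export
tidy.lnc_prognosis <- function(x, ...) x$table

#' @export
glance.lnc_prognosis <- function(x, ...) {
  tibble::tibble(
    endpoint = x$endpoint,
    n_candidates = x$n_candidates,
    n_screened = nrow(x$table),
    n_good = sum(x$table$label == "good"),
    n_bad = sum(x$table$label == "bad"),
    min_expr = x$min_expr, p_gate = x$p_gate
  )
}

#' @export
print.lnc_prognosis <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Prognostic screen (%s endpoint): %d/%d genes screened; %d good / %d bad at p < %.2g\n",
    g$endpoint, g$n_screened, g$n_candidates, g$n_good, g$n_bad, x$p_gate))
  invisible(x)
}
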