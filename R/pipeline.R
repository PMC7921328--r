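#' Pipeline configuration
#'
#' Bundles input sources and analysis thresholds for [run_pipeline()].
#' Exactly one of `paths` (on-disk cohort written by [write_cohort()]) or
#' `simulate` (a [sim_config()]) must be given. Thresholds default to the
#' conventional gates: fold change 1.5, FDR 0.05, |Rs| 0.3, OR 1, detection
#' at 0.1 FPKM and a 1-FPKM prognostic expression filter.
#'
#' @param paths Named list of input file paths (`counts`, `annotation`,
#'   `clinical`, `hallmark_gmt`, `immune_process_gmt`, `checkpoints`,
#'   `signature_scores`, `signature_matrix`), or `NULL`.
#' @param simulate A [sim_config()], or `NULL`.
#' @param fc,fdr,rs,or_gate,fpkm_detect,fpkm_prognostic Analysis gates.
#' @param top_k_edges Mediation edges kept per enriched pair.
#' @param seed Seed applied before any stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(paths = NULL, simulate = NULL,
                            fc = 1.5, fdr = 0.05, rs = 0.3, or_gate = 1,
                            fpkm_detect = 0.1, fpkm_prognostic = 1,
                            top_k_edges = 5, seed = 1L) {
  if (is.null(paths) == is.null(simulate)) {
    stop_input("exactly one of `paths` or `simulate` must be supplied")
  }
  for (nm in c("fc", "fdr", "rs", "or_gate", "fpkm_detect", "fpkm_prognostic")) {
    assert_scalar_number(get(nm), nm, lower = 1e-12)
  }
  structure(list(paths = paths, simulate = simulate,
                 fc = fc, fdr = fdr, rs = rs, or_gate = or_gate,
                 fpkm_detect = fpkm_detect, fpkm_prognostic = fpkm_prognostic,
                 top_k_edges = assert_count(top_k_edges, "top_k_edges"),
                 seed = assert_count(seed, "seed", 0L)),
            class = "pipeline_config")
}

read_cohort_paths <- function(paths) {
  need <- c("counts", "annotation", "clinical", "hallmark_gmt",
            "immune_process_gmt", "checkpoints", "signature_scores",
            "signature_matrix")
  missing <- setdiff(need, names(paths))
  if (length(missing) > 0) stop_input("paths missing: %s", paste(missing, collapse = ", "))
  list(
    counts = read_matrix_tsv(paths$counts, unit = "counts"),
    annotation = readr::read_tsv(paths$annotation, show_col_types = FALSE),
    clinical = readr::read_tsv(paths$clinical, show_col_types = FALSE),
    gene_sets = list(hallmark = read_gmt(paths$hallmark_gmt),
                     immune_process = read_gmt(paths$immune_process_gmt)),
    checkpoints = readLines(paths$checkpoints),
    signature_scores = read_matrix_tsv(paths$signature_scores),
    signature_matrix = read_matrix_tsv(paths$signature_matrix),
    truth = NULL
  )
}

stage_log <- function(manifest, stage, t0, ...) {
  info <- list(...)
  manifest$stages[[stage]] <- c(info, list(seconds = round(as.numeric(Sys.time()) - t0, 2)))
  inform(sprintf("[%s] %s", stage,
                 paste(names(info), unlist(info), sep = "=", collapse = " ")))
  manifest
}

#' Run the full lncRNA-immune interaction pipeline
#'
#' Executes, in order: FPKM normalization, lncRNA prevalence profiling,
#' negative-binomial differential expression, prognostic screening (overall
#' and disease-free endpoints), gene-set activity scoring (hallmarks and
#' immune processes), partner-set enrichment, signature-track correlation,
#' immune-cell deconvolution plus cell correlations, checkpoint
#' correlations, mediation-edge extraction and summary tables. Every stage's
#' table is written to `out_dir` before the next stage begins. Correlation
#' stages run on tumor samples only.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the run `manifest`, every stage result,
#'   and the `summary` tables.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) stop_input("`config` must come from pipeline_config()")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  manifest <- list(config = unclass(config[setdiff(names(config), c("paths", "simulate"))]),
                   r_version = as.character(getRversion()),
                   stages = list())
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      stop_input("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }

  ## load / simulate
  t0 <- as.numeric(Sys.time())
  cohort <- run_stage("input", function() {
    if (!is.null(config$simulate)) simulate_cohort(config$simulate)
    else read_cohort_paths(config$paths)
  })
  set.seed(config$seed)
  manifest$config$hash <- rlang::hash(list(manifest$config, cohort$annotation$gene_id))
  manifest <- stage_log(manifest, "input", t0,
                        n_genes = nrow(cohort$counts), n_samples = ncol(cohort$counts))

  ann <- cohort$annotation
  clin <- cohort$clinical
  tumor_ids <- clin$sample_id[clin$condition == "tumor"]
  lnc_all <- ann$gene_id[ann$biotype == "lncRNA"]
  pc_all <- ann$gene_id[ann$biotype == "protein_coding"]

  ## normalize
  t0 <- as.numeric(Sys.time())
  fpkm <- run_stage("normalize", function() to_fpkm(cohort$counts, ann))
  write_matrix_tsv(unclass_expr(fpkm), p("fpkm.tsv"))
  lg <- log2_fpkm(fpkm)
  manifest <- stage_log(manifest, "normalize", t0, n_genes = nrow(fpkm))

  ## prevalence
  t0 <- as.numeric(Sys.time())
  prev <- run_stage("prevalence", function() {
    prevalence_profile(fpkm, ann, cutoffs = c(config$fpkm_detect, 1))
  })
  readr::write_tsv(prev, p("prevalence.tsv"))
  manifest <- stage_log(manifest, "prevalence", t0, n_cutoffs = nrow(prev))

  ## differential expression (lncRNA calls drive downstream stages)
  t0 <- as.numeric(Sys.time())
  de <- run_stage("de", function() {
    differential_expression(cohort$counts, clin$condition[match(colnames(cohort$counts), clin$sample_id)],
                            fc_gate = config$fc, fdr_gate = config$fdr)
  })
  de_tab <- tidy(de)
  readr::write_tsv(de_tab, p("de.tsv"))
  de_lnc <- de_tab$gene_id[de_tab$call != "ns" & de_tab$gene_id %in% lnc_all]
  manifest <- stage_log(manifest, "de", t0, n_tested = de$n_tested,
                        n_de_lnc = length(de_lnc))

  ## prognostic screen per endpoint
  t0 <- as.numeric(Sys.time())
  prognosis <- run_stage("prognosis", function() {
    lapply(c(os = "os", dfs = "dfs"), function(ep) {
      prognostic_screen(fpkm, de_lnc, clin, endpoint = ep,
                        min_expr = config$fpkm_prognostic, p_gate = config$fdr)
    })
  })
  for (ep in names(prognosis)) readr::write_tsv(tidy(prognosis[[ep]]), p(sprintf("prognosis_%s.tsv", ep)))
  manifest <- stage_log(manifest, "prognosis", t0,
                        n_screened_os = nrow(tidy(prognosis$os)))

  ## gene-set scoring (tumor samples)
  t0 <- as.numeric(Sys.time())
  lg_t <- expression_matrix(lg[, tumor_ids, drop = FALSE], "log2FPKM")
  gsva <- run_stage("gsva", function() {
    lapply(cohort$gene_sets, function(sets) {
      gsva_scores(lg_t, restrict_sets(sets, rownames(lg_t)))
    })
  })
  for (nm in names(gsva)) write_matrix_tsv(gsva[[nm]], p(sprintf("gsva_%s.tsv", nm)), id_col = "feature")
  manifest <- stage_log(manifest, "gsva",
                        t0, n_hallmark = nrow(gsva$hallmark),
                        n_immune_process = nrow(gsva$immune_process))

  ## partner sets + enrichment
  t0 <- as.numeric(Sys.time())
  detected <- rowMeans(fpkm[, tumor_ids, drop = FALSE] >= config$fpkm_detect) > 0
  universe <- intersect(pc_all, rownames(fpkm)[detected])
  partner <- run_stage("partners", function() {
    if (length(de_lnc) == 0L) {
      tibble::tibble(lnc = character(), partner = character(), rs = numeric(),
                     p = numeric(), fdr = numeric(), significant = logical())
    } else {
      partner_sets(lg_t, de_lnc, universe, rs_gate = config$rs, fdr_gate = config$fdr)
    }
  })
  readr::write_tsv(partner, p("partners.tsv"))
  enr <- run_stage("enrichment", function() {
    if (nrow(partner) == 0L) {
      tibble::tibble(lnc = character(), collection = character(), feature = character(),
                     a = integer(), b = integer(), c = integer(), d = integer(),
                     or = numeric(), p = numeric(), fdr = numeric(),
                     enriched = logical(), test = character())
    } else {
      enrich_all(partner, cohort$gene_sets, universe = universe,
                 test = c("fisher", "hypergeometric"),
                 or_gate = config$or_gate, fdr_gate = config$fdr)
    }
  })
  readr::write_tsv(enr, p("enrichment.tsv"))
  manifest <- stage_log(manifest, "enrichment", t0,
                        n_sig_pairs = sum(partner$significant),
                        n_enriched = sum(enr$enriched))

  ## immunogenomic signature tracks
  t0 <- as.numeric(Sys.time())
  sig_cor <- run_stage("signature_tracks", function() {
    tracks <- attach_supplied_scores(cohort$signature_scores, tumor_ids)
    if (length(de_lnc) == 0L) empty_track_cor() else
      correlate_tracks(lg_t, de_lnc, tracks, rs_gate = config$rs, fdr_gate = config$fdr)
  })
  readr::write_tsv(sig_cor, p("signature_correlations.tsv"))
  manifest <- stage_log(manifest, "signature_tracks", t0,
                        n_significant = sum(sig_cor$significant))

  ## deconvolution + cell correlations
  t0 <- as.numeric(Sys.time())
  fractions <- run_stage("deconvolution", function() {
    deconvolve(fpkm[, tumor_ids, drop = FALSE], cohort$signature_matrix)
  })
  readr::write_tsv(tidy(fractions), p("cell_fractions.tsv"))
  cellcor <- run_stage("cell_correlations", function() {
    if (length(de_lnc) == 0L) {
      list(records = dplyr::rename(empty_track_cor(), cell_type = "track"),
           summary = tibble::tibble(cell_type = character(),
                                    n_positive = integer(), n_negative = integer()))
    } else {
      cell_correlations(lg_t, de_lnc, fractions, rs_gate = config$rs, fdr_gate = config$fdr)
    }
  })
  readr::write_tsv(cellcor$records, p("cell_correlations.tsv"))
  manifest <- stage_log(manifest, "deconvolution", t0,
                        n_cell_types = ncol(fractions),
                        mean_residual = round(mean(attr(fractions, "residual")), 4))

  ## checkpoint correlations
  t0 <- as.numeric(Sys.time())
  ckpt_cor <- run_stage("checkpoints", function() {
    ckpt <- intersect(cohort$checkpoints, rownames(lg_t))
    if (length(ckpt) == 0L || length(de_lnc) == 0L) empty_track_cor() else
      correlate_tracks(lg_t, de_lnc, lg_t[ckpt, , drop = FALSE],
                       rs_gate = config$rs, fdr_gate = config$fdr)
  })
  readr::write_tsv(ckpt_cor, p("checkpoint_correlations.tsv"))
  manifest <- stage_log(manifest, "checkpoints", t0,
                        n_significant = sum(ckpt_cor$significant))

  ## mediation edges
  t0 <- as.numeric(Sys.time())
  edges <- run_stage("mediation", function() {
    mediation_edges(partner, cohort$gene_sets, enr, top_k = config$top_k_edges)
  })
  readr::write_tsv(edges, p("mediation_edges.tsv"))
  manifest <- stage_log(manifest, "mediation", t0, n_edges = nrow(edges))

  ## summary tables
  t0 <- as.numeric(Sys.time())
  results <- list(manifest = manifest, cohort = cohort, fpkm = fpkm,
                  prevalence = prev, de = de, prognosis = prognosis,
                  gsva = gsva, partner = partner, enrichment = enr,
                  signature_correlations = sig_cor, fractions = fractions,
                  cell_correlations = cellcor, checkpoint_correlations = ckpt_cor,
                  mediation = edges)
  summary_tables <- run_stage("summarize", function() summarize_run(results))
  for (nm in names(summary_tables)) {
    readr::write_tsv(summary_tables[[nm]], p(sprintf("summary_%s.tsv", nm)))
  }
  manifest <- stage_log(manifest, "summarize", t0, n_tables = length(summary_tables))
  results$manifest <- manifest
  results$summary <- summary_tables
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(results)
}

empty_track_cor <- function() {
  tibble::tibble(lnc = character(), track = character(), rs = numeric(),
                 p = numeric(), fdr = numeric(), significant = logical(),
                 direction = character())
}

#' Figure-backing summary tables for a pipeline run
#'
#' Recomputable summaries of the raw record tables: per-feature counts of
#' enriched lncRNAs split by partner-correlation sign, per-signature and
#' per-cell-type positive/negative lncRNA counts, the lncRNA-process
#' network edge list (weight `-log10 FDR`), and the tripartite
#' lncRNA-cell-checkpoint edge list in which every entity passes its own
#' significance gate.
#'
#' @param results Result list from [run_pipeline()] (needs `enrichment`,
#'   `partner`, `signature_correlations`, `cell_correlations`,
#'   `checkpoint_correlations`).
#' @return Named list of tibbles: `feature_counts`, `signature_counts`,
#'   `network_edges`, `tripartite_edges`.
#' @export
summarize_run <- function(results) {
  need <- c("enrichment", "partner", "signature_correlations",
            "cell_correlations", "checkpoint_correlations")
  missing <- setdiff(need, names(results))
  if (length(missing) > 0) stop_input("summarize: missing stage output '%s'", missing[1])
  enr <- dplyr::filter(results$enrichment, .data$enriched)

  # dominant partner-correlation sign of each enriched pair
  sig <- dplyr::filter(results$partner, .data$significant)
  mean_rs <- dplyr::summarise(dplyr::group_by(sig, .data$lnc),
                              mean_rs = mean(.data$rs), .groups = "drop")
  feature_counts <- dplyr::summarise(
    dplyr::group_by(dplyr::left_join(enr, mean_rs, by = "lnc"),
                    .data$collection, .data$feature),
    n_lnc = dplyr::n_distinct(.data$lnc),
    n_positive = sum(.data$mean_rs > 0, na.rm = TRUE),
    n_negative = sum(.data$mean_rs < 0, na.rm = TRUE),
    .groups = "drop")

  sig_counts <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(results$signature_correlations, .data$significant),
                    .data$track),
    n_positive = sum(.data$direction == "positive"),
    n_negative = sum(.data$direction == "negative"),
    .groups = "drop")

  net <- dplyr::transmute(
    dplyr::filter(enr, .data$collection == "immune_process"),
    source = .data$lnc, target = .data$feature, layer = "lncRNA-process",
    weight = -log10(pmax(.data$fdr, 1e-300)))

  cell_sig <- dplyr::filter(results$cell_correlations$records, .data$significant)
  ckpt_sig <- dplyr::filter(results$checkpoint_correlations, .data$significant)
  tri <- dplyr::bind_rows(
    dplyr::transmute(cell_sig, source = .data$lnc, target = .data$cell_type,
                     layer = "lncRNA-cell", weight = .data$rs),
    dplyr::transmute(ckpt_sig, source = .data$lnc, target = .data$track,
                     layer = "lncRNA-checkpoint", weight = .data$rs))

  list(feature_counts = feature_counts, signature_counts = sig_counts,
       network_edges = net, tripartite_edges = tri)
}
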