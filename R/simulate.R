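#' Configuration for the synthetic tumor/normal cohort generator
#'
#' Builds a validated configuration for [simulate_cohort()]. Defaults describe
#' a desk-scale prostate-cancer-like cohort: 100 tumors with 20 paired
#' adjacent normals, 500 lncRNAs and 2000 protein-coding genes, an LM22-style
#' 22-cell-type signature and 26 immunogenomic signature-score tracks.
#'
#' @param n_tumor,n_normal Tumor and paired-normal sample counts
#'   (`n_normal <= n_tumor`).
#' @param n_lnc,n_pc Numbers of lncRNA and protein-coding genes.
#' @param n_cell_types Immune cell types in the signature matrix (>= 2).
#' @param n_signatures Immunogenomic signature-score tracks.
#' @param de_fraction Fraction of lncRNAs planted as differentially expressed.
#' @param lfc_range Length-2 range of planted |log2 fold change|.
#' @param dispersion_meanlog,dispersion_sdlog Log-normal parameters of the
#'   gene-wise NB dispersion alpha (variance = mu + alpha * mu^2).
#' @param n_latent Latent immune-activity factors coupling lncRNAs to gene
#'   modules and signature tracks.
#' @param lnc_per_factor lncRNAs coupled to each latent factor.
#' @param coupling_strength Loading (log2 units per factor SD) of coupled
#'   lncRNAs and module genes on their latent factor; 0 removes all coupling.
#' @param n_prognostic Planted prognostic lncRNAs (ignored when
#'   `surv_beta = 0`).
#' @param surv_beta Log hazard ratio per SD of expression for planted
#'   prognostic lncRNAs.
#' @param prognostic_signs Signs recycled over the planted prognostic genes
#'   (+1 = hazardous / bad prognosis, -1 = protective).
#' @param censor_rate Target censoring fraction (exponential censoring whose
#'   rate is matched to the baseline event rate).
#' @param n_cell_coupled lncRNAs coupled to immune-cell fractions.
#' @param mixing_noise SD of multiplicative log-normal noise on
#'   signature-gene expression around the signature-matrix mixture.
#' @param n_hallmark,n_immune_process Numbers of hallmark-like and
#'   immune-process-like gene sets emitted.
#' @param markers_per_type Exclusive marker genes per immune cell type in the
#'   signature matrix.
#' @param seed RNG seed; a fixed seed makes [simulate_cohort()] output
#'   byte-identical across runs.
#' @return A list of class `sim_config`.
#' @seealso [simulate_cohort()], [null_config()]
#' @export
sim_config <- function(n_tumor = 100, n_normal = 20,
                       n_lnc = 500, n_pc = 2000,
                       n_cell_types = 22, n_signatures = 26,
                       de_fraction = 0.1, lfc_range = c(1, 2.5),
                       dispersion_meanlog = log(0.1), dispersion_sdlog = 0.5,
                       n_latent = 5, lnc_per_factor = 2,
                       coupling_strength = 1,
                       n_prognostic = 5, surv_beta = 0.7,
                       prognostic_signs = 1,
                       censor_rate = 0.3,
                       n_cell_coupled = 2,
                       mixing_noise = 0.1,
                       n_hallmark = 50, n_immune_process = 95,
                       markers_per_type = 10,
                       seed = 1L) {
  cfg <- list(
    n_tumor = assert_count(n_tumor, "n_tumor", 2L),
    n_normal = assert_count(n_normal, "n_normal", 2L),
    n_lnc = assert_count(n_lnc, "n_lnc", 10L),
    n_pc = assert_count(n_pc, "n_pc", 50L),
    n_cell_types = assert_count(n_cell_types, "n_cell_types", 2L),
    n_signatures = assert_count(n_signatures, "n_signatures", 1L),
    de_fraction = assert_scalar_number(de_fraction, "de_fraction", 0, 1),
    lfc_range = sort(lfc_range),
    dispersion_meanlog = assert_scalar_number(dispersion_meanlog, "dispersion_meanlog"),
    dispersion_sdlog = assert_scalar_number(dispersion_sdlog, "dispersion_sdlog", 0),
    n_latent = assert_count(n_latent, "n_latent", 0L),
    lnc_per_factor = assert_count(lnc_per_factor, "lnc_per_factor", 1L),
    coupling_strength = assert_scalar_number(coupling_strength, "coupling_strength", 0),
    n_prognostic = assert_count(n_prognostic, "n_prognostic", 0L),
    surv_beta = assert_scalar_number(surv_beta, "surv_beta"),
    prognostic_signs = sign(prognostic_signs),
    censor_rate = assert_scalar_number(censor_rate, "censor_rate", 0, 0.95),
    n_cell_coupled = assert_count(n_cell_coupled, "n_cell_coupled", 0L),
    mixing_noise = assert_scalar_number(mixing_noise, "mixing_noise", 0),
    n_hallmark = assert_count(n_hallmark, "n_hallmark", 1L),
    n_immune_process = assert_count(n_immune_process, "n_immune_process", 1L),
    markers_per_type = assert_count(markers_per_type, "markers_per_type", 2L),
    seed = assert_count(seed, "seed", 0L)
  )
  if (length(cfg$lfc_range) != 2L || any(cfg$lfc_range < 0)) {
    stop_input("`lfc_range` must be two non-negative numbers")
  }
  if (cfg$n_normal > cfg$n_tumor) stop_input("`n_normal` must not exceed `n_tumor`")
  if (cfg$n_cell_types < 2L) stop_input("`n_cell_types` < 2: deconvolution undefined")
  structure(cfg, class = "sim_config")
}

#' Global-null generator configuration
#'
#' Convenience wrapper: no differential expression, no lncRNA-module
#' coupling, no survival effect. Downstream stages should then behave as a
#' global null.
#'
#' @param ... Passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
null_config <- function(...) {
  sim_config(de_fraction = 0, coupling_strength = 0, surv_beta = 0,
             n_cell_coupled = 0, ...)
}

# Dirichlet(1,...,1) rows
rdirichlet1 <- function(n, k) {
  g <- matrix(rexp(n * k), n, k)
  g / rowSums(g)
}

#' Simulate a tumor/normal cohort with planted immune structure
#'
#' Generates a full synthetic cohort: NB counts for lncRNA and protein-coding
#' genes over tumor and paired normal samples, gene annotation, a clinical
#' table with two survival endpoints, hallmark-like and immune-process-like
#' gene-set collections, per-sample immunogenomic signature-score tracks, an
#' identifiable cell-type signature matrix, and the planted ground truth.
#'
#' The generative model, on the log2 count-mean scale:
#' baseline + patient effect (shared by each tumor/normal pair) +
#' condition effect (planted DE lncRNAs only) + latent-factor loadings
#' (coupled lncRNAs, their module genes and checkpoint genes) on per-sample
#' factor activities. Factor activities are standard normal with a one-SD
#' higher mean in tumor samples: immune programs run hotter in tumors, so a
#' factor-coupled lncRNA is itself differential with effective
#' `log2FC = sign * coupling_strength` (recorded as its truth fold change). Counts are NB with gene-wise
#' log-normal dispersion. Signature-marker genes instead follow
#' signature-matrix x per-sample Dirichlet mixing fractions with
#' multiplicative log-normal noise, Poisson-sampled to counts (every sample,
#' tumor or normal, carries an immune infiltrate, so marker expression is not
#' condition-dependent). Survival times are
#' exponential with per-sample log hazard equal to the sum of planted betas
#' times standardized prognostic-gene expression; censoring is exponential
#' with rate matched to the target censoring fraction.
#'
#' @param config A [sim_config()].
#' @return A list of class `lnc_cohort` with elements `counts` (genes x
#'   samples, unit-tagged), `annotation`, `clinical` (tibbles), `gene_sets`
#'   (named list: `hallmark`, `immune_process`), `checkpoints`,
#'   `signature_scores` (tumor samples x tracks), `signature_matrix`
#'   (marker genes x cell types, FPKM scale), and `truth` (class
#'   `lnc_truth`): planted DE genes, prognostic genes, coupled lncRNA-set
#'   pairs, signature-track and cell-fraction loadings, and the true mixing
#'   fractions.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_tumor = 20, n_normal = 5,
#'                                      n_lnc = 50, n_pc = 300, seed = 7))
#' dim(cohort$counts)
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) stop_input("`config` must come from sim_config()")
  cfg <- config
  set.seed(cfg$seed)

  n_samp <- cfg$n_tumor + cfg$n_normal
  tumor_ids <- sprintf("T%03d", seq_len(cfg$n_tumor))
  normal_ids <- sprintf("N%03d", seq_len(cfg$n_normal))
  sample_ids <- c(tumor_ids, normal_ids)
  is_tumor <- c(rep(TRUE, cfg$n_tumor), rep(FALSE, cfg$n_normal))
  # normal i is the adjacent tissue of the patient of tumor i
  patient <- c(sprintf("P%03d", seq_len(cfg$n_tumor)),
               sprintf("P%03d", seq_len(cfg$n_normal)))

  lnc_ids <- sprintf("LNC%04d", seq_len(cfg$n_lnc))
  pc_ids <- sprintf("PC%04d", seq_len(cfg$n_pc))

  ## ---- partition protein-coding genes ----
  n_sig_genes <- cfg$n_cell_types * cfg$markers_per_type
  module_sizes_h <- if (cfg$n_latent > 0) rep(20L, cfg$n_latent) else integer(0)
  module_sizes_p <- if (cfg$n_latent > 0) rep(15L, cfg$n_latent) else integer(0)
  n_module <- sum(module_sizes_h) + sum(module_sizes_p)
  n_ckpt <- length(checkpoint_genes())
  if (n_module + n_sig_genes + n_ckpt + 100L > cfg$n_pc) {
    stop_input("n_pc too small for the requested modules and signature genes")
  }
  idx <- seq_len(cfg$n_pc)
  module_idx <- idx[seq_len(n_module)]
  sig_idx <- idx[(cfg$n_pc - n_sig_genes + 1L):cfg$n_pc]
  ckpt_idx <- idx[(cfg$n_pc - n_sig_genes - n_ckpt + 1L):(cfg$n_pc - n_sig_genes)]
  pool_idx <- setdiff(idx, c(module_idx, sig_idx, ckpt_idx))
  pc_ids[ckpt_idx] <- checkpoint_genes()
  gene_ids <- c(lnc_ids, pc_ids)
  n_gene <- length(gene_ids)

  ## ---- gene sets ----
  gene_sets <- list(hallmark = list(), immune_process = list())
  hall_names <- sprintf("HALLMARK_SET_%02d", seq_len(cfg$n_hallmark))
  proc_names <- sprintf("IMMUNE_PROCESS_%03d", seq_len(cfg$n_immune_process))
  max_size <- 40L
  if (max_size > cfg$n_pc) stop_input("gene-set sizes exceed n_pc")
  off <- 0L
  for (f in seq_len(cfg$n_latent)) {
    gene_sets$hallmark[[hall_names[f]]] <- pc_ids[module_idx[off + seq_len(module_sizes_h[f])]]
    off <- off + module_sizes_h[f]
  }
  for (f in seq_len(cfg$n_latent)) {
    gene_sets$immune_process[[proc_names[f]]] <- pc_ids[module_idx[off + seq_len(module_sizes_p[f])]]
    off <- off + module_sizes_p[f]
  }
  for (s in setdiff(seq_len(cfg$n_hallmark), seq_len(cfg$n_latent))) {
    gene_sets$hallmark[[hall_names[s]]] <-
      pc_ids[sample(pool_idx, sample(15:max_size, 1))]
  }
  for (s in setdiff(seq_len(cfg$n_immune_process), seq_len(cfg$n_latent))) {
    gene_sets$immune_process[[proc_names[s]]] <-
      pc_ids[sample(pool_idx, sample(10:30, 1))]
  }
  gene_sets$hallmark <- gene_sets$hallmark[hall_names]
  gene_sets$immune_process <- gene_sets$immune_process[proc_names]

  ## ---- gene baselines (needed before couplings are placed) ----
  base_log2 <- c(rnorm(cfg$n_lnc, 3, 1.5), rnorm(cfg$n_pc, 5, 1.5))
  lengths_bp <- round(exp(runif(n_gene, log(200), log(1e5))))
  alpha <- rlnorm(n_gene, cfg$dispersion_meanlog, cfg$dispersion_sdlog)
  # couplings and survival effects land on decently expressed lncRNAs:
  # an immune- or prognosis-linked lncRNA must be measurable to be planted
  pick_expressed <- function(pool, need) {
    if (need == 0L || length(pool) == 0L) return(integer(0))
    ord <- pool[order(-base_log2[pool])]
    cand <- head(ord, max(need, min(length(ord), 2L * need)))
    sample(cand, min(need, length(cand)))
  }

  ## ---- planted DE lncRNAs ----
  n_de <- round(cfg$de_fraction * cfg$n_lnc)
  de_idx <- if (n_de > 0) sample(cfg$n_lnc, n_de) else integer(0)
  de_lfc <- numeric(cfg$n_lnc)
  if (n_de > 0) {
    mag <- runif(n_de, cfg$lfc_range[1], cfg$lfc_range[2])
    sgn <- rep_len(c(1, -1), n_de)
    de_lfc[de_idx] <- sgn * mag
  }

  ## ---- latent factors and couplings ----
  # immune-activity factors run one SD hotter in tumors, so factor-coupled
  # lncRNAs (and module/checkpoint genes) are differential through the factor
  factor_shift <- 1
  z <- if (cfg$n_latent > 0) {
    matrix(rnorm(cfg$n_latent * n_samp), cfg$n_latent, n_samp) +
      rep(factor_shift, cfg$n_latent) %o% as.numeric(is_tumor)
  } else matrix(0, 0, n_samp)
  loading <- matrix(0, n_gene, n_samp) # log2 offsets added below
  coupled <- tibble::tibble(lnc = character(), set = character(),
                            collection = character(), sign = numeric())
  sig_load <- tibble::tibble(lnc = character(), track = character(), sign = numeric())
  # couplings are planted on differential lncRNAs (the downstream screen only
  # correlates DE calls); fall back to the full lncRNA pool when none planted
  couple_pool <- if (n_de > 0) de_idx else seq_len(cfg$n_lnc)
  lnc_factor <- list()
  if (cfg$coupling_strength > 0 && cfg$n_latent > 0) {
    need <- cfg$n_latent * cfg$lnc_per_factor
    if (length(couple_pool) < need) stop_input("not enough lncRNAs for requested couplings")
    picked <- matrix(pick_expressed(couple_pool, need), nrow = cfg$n_latent)
    for (f in seq_len(cfg$n_latent)) {
      lncs <- picked[f, ]
      signs <- rep_len(c(1, -1), length(lncs))
      lnc_factor[[f]] <- lncs
      for (k in seq_along(lncs)) {
        # the factor's tumor shift supplies the DE effect for coupled lncRNAs;
        # drop their independently sampled fold change to avoid double counting
        de_lfc[lncs[k]] <- signs[k] * cfg$coupling_strength * factor_shift
        loading[lncs[k], ] <- loading[lncs[k], ] +
          signs[k] * cfg$coupling_strength * (z[f, ] -
            factor_shift * as.numeric(is_tumor))
        coupled <- dplyr::bind_rows(coupled, tibble::tibble(
          lnc = lnc_ids[lncs[k]],
          set = c(hall_names[f], proc_names[f]),
          collection = c("hallmark", "immune_process"),
          sign = signs[k]))
      }
      mod_genes <- c(gene_sets$hallmark[[hall_names[f]]],
                     gene_sets$immune_process[[proc_names[f]]])
      gi <- match(mod_genes, gene_ids)
      loading[gi, ] <- loading[gi, ] +
        rep(cfg$coupling_strength, length(gi)) %o% z[f, ]
      # signature track f follows factor f; coupled lncRNAs load on it
      sig_load <- dplyr::bind_rows(sig_load, tibble::tibble(
        lnc = lnc_ids[lncs], track = sprintf("IGS%02d", f), sign = signs))
    }
    # checkpoint genes ride factor 1 so factor-1 lncRNAs correlate with them
    loading[match(checkpoint_genes(), gene_ids), ] <-
      loading[match(checkpoint_genes(), gene_ids), ] +
      rep(cfg$coupling_strength, n_ckpt) %o% z[1, ]
  }

  ## ---- true mixing fractions (every sample carries an immune infiltrate) ----
  fractions <- rdirichlet1(n_samp, cfg$n_cell_types)
  cell_names <- if (cfg$n_cell_types == 22L) lm22_cell_types() else
    sprintf("Cell type %02d", seq_len(cfg$n_cell_types))
  dimnames(fractions) <- list(sample_ids, cell_names)

  # lncRNAs coupled to a cell-type fraction (standardized, tumor samples)
  cell_load <- tibble::tibble(lnc = character(), cell_type = character(), sign = numeric())
  used <- unlist(lnc_factor)
  free2 <- setdiff(couple_pool, used)
  if (cfg$n_cell_coupled > 0 && cfg$coupling_strength > 0) {
    lncs <- pick_expressed(free2, min(cfg$n_cell_coupled, length(free2)))
    types <- sample(cfg$n_cell_types, length(lncs), replace = TRUE)
    signs <- rep_len(c(1, -1), length(lncs))
    for (k in seq_along(lncs)) {
      fz <- as.numeric(scale(fractions[tumor_ids, types[k]]))
      loading[lncs[k], seq_len(cfg$n_tumor)] <-
        loading[lncs[k], seq_len(cfg$n_tumor)] + signs[k] * cfg$coupling_strength * fz
    }
    cell_load <- tibble::tibble(lnc = lnc_ids[lncs],
                                cell_type = cell_names[types], sign = signs)
  }

  ## ---- NB counts ----
  pat_eff <- rnorm(cfg$n_tumor, 0, 0.3) # per patient, shared by the pair
  samp_pat_eff <- c(pat_eff, pat_eff[seq_len(cfg$n_normal)])
  cond_eff <- c(de_lfc, numeric(cfg$n_pc)) %o% as.numeric(is_tumor)
  log2_mu <- base_log2 + cond_eff + loading +
    rep(1, n_gene) %o% samp_pat_eff
  mu <- 2^log2_mu
  counts <- matrix(rnbinom(n_gene * n_samp, mu = mu, size = rep(1 / alpha, n_samp)),
                   n_gene, n_samp, dimnames = list(gene_ids, sample_ids))

  ## ---- signature genes: mixture-driven expression in tumors ----
  # signature matrix on an FPKM-like scale with exclusive marker blocks
  # markers ~100x over background, scaled so the signature block stays a
  # minor share of the library (immune markers must not drive library size)
  S <- matrix(runif(n_sig_genes * cfg$n_cell_types, 0.5, 2),
              n_sig_genes, cfg$n_cell_types)
  for (k in seq_len(cfg$n_cell_types)) {
    rows <- (k - 1L) * cfg$markers_per_type + seq_len(cfg$markers_per_type)
    S[rows, k] <- runif(cfg$markers_per_type, 50, 150)
  }
  sig_gene_ids <- pc_ids[sig_idx]
  dimnames(S) <- list(sig_gene_ids, cell_names)
  lib_nom <- 2e7
  # marker transcripts get realistic cDNA lengths so their count share stays sane
  lengths_bp[match(sig_gene_ids, gene_ids)] <-
    round(exp(runif(n_sig_genes, log(500), log(5000))))
  sig_len <- lengths_bp[match(sig_gene_ids, gene_ids)]
  expected_fpkm <- S %*% t(fractions) # sig genes x all samples
  noise <- matrix(exp(rnorm(length(expected_fpkm), 0, cfg$mixing_noise)),
                  nrow(expected_fpkm), ncol(expected_fpkm))
  mu_sig <- expected_fpkm * noise * sig_len * lib_nom / 1e9
  counts[sig_gene_ids, ] <- rpois(length(mu_sig), mu_sig)

  ## ---- signature-score tracks (tumor samples) ----
  track_names <- sprintf("IGS%02d", seq_len(cfg$n_signatures))
  scores <- matrix(rnorm(cfg$n_tumor * cfg$n_signatures), cfg$n_tumor, cfg$n_signatures,
                   dimnames = list(tumor_ids, track_names))
  if (cfg$coupling_strength > 0 && cfg$n_latent > 0) {
    for (f in seq_len(min(cfg$n_latent, cfg$n_signatures))) {
      scores[, f] <- cfg$coupling_strength * z[f, seq_len(cfg$n_tumor)] +
        rnorm(cfg$n_tumor, 0, 0.5)
    }
  }

  ## ---- survival (tumor samples, two endpoints) ----
  prog <- tibble::tibble(gene_id = character(), beta = numeric())
  lp <- numeric(cfg$n_tumor)
  if (cfg$surv_beta != 0 && cfg$n_prognostic > 0) {
    cand <- if (n_de > 0) de_idx else seq_len(cfg$n_lnc)
    pidx <- pick_expressed(cand, min(cfg$n_prognostic, length(cand)))
    betas <- cfg$surv_beta * rep_len(cfg$prognostic_signs, length(pidx))
    for (k in seq_along(pidx)) {
      x <- log2(counts[pidx[k], tumor_ids] + 1)
      lp <- lp + betas[k] * as.numeric(scale(x))
    }
    prog <- tibble::tibble(gene_id = lnc_ids[pidx], beta = betas)
  }
  gen_endpoint <- function(base_rate) {
    h <- base_rate * exp(lp)
    t_ev <- rexp(cfg$n_tumor, h)
    rate_c <- base_rate * cfg$censor_rate / max(1 - cfg$censor_rate, 0.05)
    t_c <- if (cfg$censor_rate > 0) rexp(cfg$n_tumor, rate_c) else rep(Inf, cfg$n_tumor)
    list(time = pmax(pmin(t_ev, t_c), 1e-6), event = as.integer(t_ev <= t_c))
  }
  os <- gen_endpoint(0.10)
  dfs <- gen_endpoint(0.15)

  clinical <- tibble::tibble(
    sample_id = sample_ids,
    patient_id = patient,
    condition = ifelse(is_tumor, "tumor", "normal"),
    os_time = c(os$time, rep(NA_real_, cfg$n_normal)),
    os_event = c(os$event, rep(NA_integer_, cfg$n_normal)),
    dfs_time = c(dfs$time, rep(NA_real_, cfg$n_normal)),
    dfs_event = c(dfs$event, rep(NA_integer_, cfg$n_normal))
  )
  annotation <- tibble::tibble(
    gene_id = gene_ids,
    biotype = c(rep("lncRNA", cfg$n_lnc), rep("protein_coding", cfg$n_pc)),
    length_bp = lengths_bp
  )
  truth <- structure(list(
    de_genes = tibble::tibble(gene_id = lnc_ids[de_lfc != 0],
                              log2fc = de_lfc[de_lfc != 0]),
    prognostic_genes = prog,
    coupled_pairs = coupled,
    signature_loadings = sig_load,
    cell_loadings = cell_load,
    fractions = fractions
  ), class = "lnc_truth")

  structure(list(
    counts = expression_matrix(counts, "counts"),
    annotation = annotation,
    clinical = clinical,
    gene_sets = gene_sets,
    checkpoints = checkpoint_genes(),
    signature_scores = scores,
    signature_matrix = S,
    truth = truth,
    config = cfg
  ), class = "lnc_cohort")
}

#' Write a simulated cohort to disk as plain-text files
#'
#' Serializes every component of an [simulate_cohort()] result: counts,
#' annotation and clinical TSVs, one GMT per gene-set collection, a
#' checkpoint gene list, signature-score and signature-matrix TSVs, and the
#' planted truth as JSON.
#'
#' @param cohort An `lnc_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "lnc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_matrix_tsv(unclass_expr(cohort$counts), p("counts.tsv"))
  readr::write_tsv(cohort$annotation, p("annotation.tsv"))
  readr::write_tsv(cohort$clinical, p("clinical.tsv"))
  write_gmt(cohort$gene_sets$hallmark, p("hallmark.gmt"))
  write_gmt(cohort$gene_sets$immune_process, p("immune_process.gmt"))
  writeLines(cohort$checkpoints, p("checkpoints.txt"))
  write_matrix_tsv(cohort$signature_scores, p("signature_scores.tsv"), id_col = "sample_id")
  write_matrix_tsv(cohort$signature_matrix, p("signature_matrix.tsv"))
  truth <- cohort$truth
  truth$fractions <- cbind(
    tibble::tibble(sample_id = rownames(truth$fractions)),
    tibble::as_tibble(truth$fractions))
  jsonlite::write_json(unclass(truth), p("truth.json"), dataframe = "columns", digits = NA)
  invisible(dir)
}

unclass_expr <- function(x) {
  attr(x, "expr_unit") <- NULL
  x
}
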