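test_that("FPKM follows the unit definition and its algebraic identity", {
  # count 10, length 1000 bp, library 1e6 -> FPKM 10; zero stays zero
  m <- matrix(c(10, 999990), 2, 1, dimnames = list(c("a", "b"), "s1"))
  f <- to_fpkm(as_expression_matrix(m, "counts"), c(a = 1000, b = 1e6))
  expect_equal(f["a", "s1"], 10)
  m2 <- matrix(c(0, 100), 2, 1, dimnames = list(c("a", "b"), "s1"))
  f2 <- to_fpkm(as_expression_matrix(m2, "counts"), c(a = 1000, b = 500))
  expect_equal(f2["a", "s1"], 0)
  # per sample, sum_i FPKM * length = 1e9, for random matrices
  set.seed(1)
  cm <- matrix(rpois(15, 40) + 1, 5, 3,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  len <- setNames(sample(200:5000, 5), paste0("g", 1:5))
  ff <- to_fpkm(as_expression_matrix(cm, "counts"), len)
  expect_equal(unname(colSums(ff * len)), rep(1e9, 3))
})

test_that("FPKM rejects zero libraries and missing lengths by name", {
  m <- matrix(c(5, 0), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  m[, 2] <- 0
  expect_error(to_fpkm(as_expression_matrix(m, "counts"), c(a = 100, b = 100)), "s2")
  expect_error(to_fpkm(as_expression_matrix(m[, 1, drop = FALSE], "counts"),
                       c(a = 100)), "missing")
})

test_that("prevalence profile matches an exhaustive per-gene recount", {
  set.seed(3)
  m <- matrix(rexp(100, 1), 10, 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:10)))
  ann <- tibble::tibble(gene_id = paste0("g", 1:10),
                        biotype = rep(c("lncRNA", "protein_coding"), 5))
  fp <- as_expression_matrix(m, "FPKM")
  prof <- prevalence_profile(fp, ann, cutoffs = c(0.1, 0.5, 1))
  lnc <- ann$gene_id[ann$biotype == "lncRNA"]
  for (r in seq_len(nrow(prof))) {
    co <- prof$cutoff[r]
    per_gene <- sapply(lnc, function(g) sum(m[g, ] >= co))
    expect_equal(prof$frac_detected_any[r], mean(per_gene > 0))
    expect_equal(prof$mean_frac_samples[r], mean(per_gene / 10))
    expect_equal(prof$frac_broad[r], mean(per_gene / 10 > 0.9))
    expect_equal(prof$frac_narrow[r], mean(per_gene / 10 < 0.1))
  }
  # degenerate inputs
  z <- as_expression_matrix(matrix(0, 2, 3, dimnames = list(lnc[1:2], paste0("s", 1:3))), "FPKM")
  p0 <- prevalence_profile(z, ann[1:2, ], cutoffs = 0.1)
  expect_equal(p0$frac_detected_any, 0)
  expect_error(prevalence_profile(fp, ann, biotype = "rRNA"), "biotype")
})

test_that("prevalence fractions are monotone non-increasing in the cutoff", {
  set.seed(9)
  m <- matrix(rexp(400, 2), 40, 10,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:10)))
  ann <- tibble::tibble(gene_id = paste0("g", 1:40), biotype = "lncRNA")
  prof <- prevalence_profile(as_expression_matrix(m, "FPKM"), ann,
                             cutoffs = c(0.05, 0.1, 0.5, 1, 2))
  expect_true(all(diff(prof$frac_detected_any) <= 0))
  expect_true(all(diff(prof$mean_frac_samples) <= 0))
})

test_that("DE calls respect their gates and survive row/column permutation", {
  co <- simulate_cohort(sim_config(n_tumor = 30, n_normal = 10, n_lnc = 60,
                                   n_pc = 600, n_cell_types = 4,
                                   markers_per_type = 4, n_latent = 2,
                                   n_hallmark = 6, n_immune_process = 6, seed = 21))
  cond <- co$clinical$condition
  de <- differential_expression(co$counts, cond)
  tab <- tidy(de)
  up <- tab[tab$call == "up", ]
  dn <- tab[tab$call == "down", ]
  expect_true(all(up$log2fc > log2(1.5) & up$fdr < 0.05))
  expect_true(all(dn$log2fc < -log2(1.5) & dn$fdr < 0.05))
  # BH never decreases p
  expect_true(all(tab$fdr >= tab$p - 1e-12, na.rm = TRUE))
  # permutation invariance
  set.seed(1)
  gi <- sample(nrow(co$counts)); si <- sample(ncol(co$counts))
  de2 <- differential_expression(
    as_expression_matrix(unclass(co$counts)[gi, si], "counts"), cond[si])
  t2 <- tidy(de2)
  t2 <- t2[match(tab$gene_id, t2$gene_id), ]
  expect_equal(tab$log2fc, t2$log2fc)
  expect_equal(tab$p, t2$p)
  expect_equal(as.character(tab$call), as.character(t2$call))
})

test_that("planted DE genes are recovered with the right sign", {
  co <- simulate_cohort(sim_config(n_tumor = 40, n_normal = 20, n_lnc = 100,
                                   n_pc = 700, n_cell_types = 4,
                                   markers_per_type = 4, n_latent = 2,
                                   n_hallmark = 6, n_immune_process = 6,
                                   de_fraction = 0.2, lfc_range = c(1.5, 2.5),
                                   seed = 8))
  tab <- tidy(differential_expression(co$counts, co$clinical$condition))
  tr <- dplyr::filter(co$truth$de_genes, abs(.data$log2fc) >= 1.5)
  got <- tab[match(tr$gene_id, tab$gene_id), ]
  expect_gt(mean(got$call != "ns"), 0.85)
  called <- got$call != "ns"
  expect_true(all(sign(got$log2fc[called]) == sign(tr$log2fc[called])))
})

test_that("DE requires two samples per condition and two levels", {
  m <- tiny_counts(n_samp = 4)
  expect_error(differential_expression(m, c("tumor", "tumor", "tumor", "normal")),
               ">= 2 samples")
  expect_error(differential_expression(m, rep("tumor", 4)), "two condition levels")
})

test_that("cohort-exclusive genes are exactly those called nowhere else", {
  mk <- function(genes, calls) tibble::tibble(gene_id = genes, call = calls)
  des <- list(
    prad = mk(c("a", "b", "c"), c("up", "down", "ns")),
    brca = mk(c("a", "b", "c"), c("up", "ns", "ns")),
    luad = mk(c("a", "b", "c"), c("ns", "ns", "up"))
  )
  expect_equal(cross_cohort_exclusivity(des, "prad"), "b")
  expect_error(cross_cohort_exclusivity(des, "coad"), "absent")
  expect_error(cross_cohort_exclusivity(des["prad"], "prad"), "2 cohorts")
  # three simulated cohorts over the same gene space: the exclusivity set
  # must equal the brute-force set difference of the call sets
  cos <- lapply(c(101, 102, 103), function(s) {
    simulate_cohort(sim_config(n_tumor = 30, n_normal = 10, n_lnc = 60,
                               n_pc = 600, n_cell_types = 4, markers_per_type = 4,
                               n_latent = 1, n_hallmark = 5, n_immune_process = 5,
                               de_fraction = 0.1, lfc_range = c(2, 2.5), seed = s))
  })
  tabs <- lapply(cos, function(co)
    tidy(differential_expression(co$counts, co$clinical$condition)))
  names(tabs) <- c("c1", "c2", "c3")
  excl <- cross_cohort_exclusivity(tabs, "c1")
  brute <- Filter(function(g) {
    in_c1 <- tabs$c1$call[tabs$c1$gene_id == g] != "ns"
    in_others <- any(tabs$c2$call[tabs$c2$gene_id == g] != "ns") ||
      any(tabs$c3$call[tabs$c3$gene_id == g] != "ns")
    isTRUE(in_c1) && !in_others
  }, unique(tabs$c1$gene_id))
  expect_setequal(excl, brute)
})
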