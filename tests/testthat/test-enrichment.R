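test_that("spearman matches perfect monotone cases and the hand-rank oracle", {
  expect_equal(spearman(1:4, c(10, 20, 30, 40))$rs, 1)
  expect_equal(spearman(1:4, c(40, 30, 20, 10))$rs, -1)
  set.seed(10)
  for (i in 1:100) {
    n <- sample(5:15, 1)
    x <- sample(1:6, n, replace = TRUE) # heavy ties
    y <- sample(1:6, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(spearman(x, y)$rs, oracle_spearman(x, y), tolerance = 1e-12)
  }
  # constant vector yields the undefined sentinel
  expect_true(is.na(spearman(rep(1, 5), 1:5)$rs))
  expect_error(spearman(1:3, 1:3), "4 complete")
})

test_that("contingency construction equals direct set algebra", {
  expect_equal(build_contingency(letters[1:5], letters[1:5], letters[1:10]),
               c(a = 5, b = 0, c = 0, d = 5))
  expect_equal(build_contingency(letters[1:5], letters[6:10], letters[1:10]),
               c(a = 0, b = 5, c = 5, d = 0))
  set.seed(4)
  for (i in 1:50) {
    u <- sample(letters, sample(10:20, 1))
    feat <- sample(u, sample(1:length(u), 1))
    part <- sample(u, sample(0:length(u), 1))
    tab <- build_contingency(feat, part, u)
    expect_equal(tab[["a"]], length(intersect(part, feat)))
    expect_equal(tab[["b"]], length(setdiff(part, feat)))
    expect_equal(tab[["c"]], length(setdiff(feat, part)))
    expect_equal(tab[["d"]], length(setdiff(u, union(part, feat))))
    expect_equal(sum(tab), length(u))
  }
  expect_error(build_contingency("a", "a", character(0)), "empty universe")
})

test_that("exact enrichment p-values and odds ratios match their closed forms", {
  # perfect enrichment: p = 1 / C(10, 5)
  r <- enrichment_test(c(a = 5, b = 0, c = 0, d = 5))
  expect_equal(r$p, 1 / choose(10, 5))
  # plain odds ratio
  expect_equal(enrichment_test(c(a = 2, b = 1, c = 1, d = 2))$or, 4)
  # Haldane-Anscombe display correction when a zero cell appears
  expect_equal(enrichment_test(c(a = 2, b = 0, c = 1, d = 2))$or,
               (2.5 * 2.5) / (0.5 * 1.5))
  # fisher and hypergeometric expose the same one-sided tail
  tab <- c(a = 4, b = 3, c = 2, d = 6)
  expect_equal(enrichment_test(tab, "fisher")$p,
               enrichment_test(tab, "hypergeometric")$p)
  # against stats::fisher.test one-sided greater
  expect_equal(enrichment_test(tab)$p,
               stats::fisher.test(matrix(c(4, 2, 3, 6), 2), alternative = "greater")$p.value)
  expect_error(enrichment_test(c(a = -1, b = 0, c = 0, d = 1)), "negative")
})

test_that("enrichment p equals choose()-based enumeration on random tables", {
  set.seed(11)
  for (i in 1:200) {
    tab <- c(a = sample(0:8, 1), b = sample(0:8, 1),
             c = sample(0:8, 1), d = sample(0:8, 1))
    if (sum(tab) == 0) next
    expect_equal(enrichment_test(tab)$p,
                 oracle_hyper_p(tab[["a"]], tab[["b"]], tab[["c"]], tab[["d"]]),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment equals the brute-force reference", {
  set.seed(13)
  for (i in 1:50) {
    p <- runif(sample(5:200, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  }
})

test_that("partner screening is null-calibrated and order-invariant", {
  co <- simulate_cohort(null_config(n_tumor = 60, n_normal = 8, n_lnc = 40,
                                    n_pc = 600, n_cell_types = 4, markers_per_type = 4,
                                    n_latent = 2, n_hallmark = 5, n_immune_process = 5,
                                    seed = 44))
  fpkm <- to_fpkm(co$counts, co$annotation)
  lg <- as_expression_matrix(log2(unclass(fpkm) + 1), "log2FPKM")
  tum <- co$clinical$sample_id[co$clinical$condition == "tumor"]
  lgt <- as_expression_matrix(unclass(lg)[, tum], "log2FPKM")
  lnc <- co$annotation$gene_id[co$annotation$biotype == "lncRNA"][1:10]
  pc <- co$annotation$gene_id[co$annotation$biotype == "protein_coding"]
  pt <- partner_sets(lgt, lnc, pc)
  expect_lt(mean(pt$significant), 0.01) # double gate is strongly conservative
  # order invariance of the candidate universe
  pt2 <- partner_sets(lgt, lnc, rev(pc))
  m1 <- pt[order(pt$lnc, pt$partner), ]
  m2 <- pt2[order(pt2$lnc, pt2$partner), ]
  expect_equal(m1$rs, m2$rs)
  expect_equal(m1$fdr, m2$fdr)
  expect_error(partner_sets(lgt, lnc, character(0)), "empty candidate")
  expect_error(partner_sets(lgt, lnc, c(pc, lnc[1])), "disjoint")
})

test_that("planted couplings drive partner sets and enrichment, decoys stay silent", {
  co <- simulate_cohort(sim_config(n_tumor = 100, n_normal = 10, n_lnc = 80,
                                   n_pc = 800, n_cell_types = 4, markers_per_type = 4,
                                   n_latent = 2, n_hallmark = 8, n_immune_process = 8,
                                   coupling_strength = 1.5, seed = 55))
  fpkm <- to_fpkm(co$counts, co$annotation)
  tum <- co$clinical$sample_id[co$clinical$condition == "tumor"]
  lgt <- as_expression_matrix(log2(unclass(fpkm)[, tum] + 1), "log2FPKM")
  cp <- co$truth$coupled_pairs
  coupled_lnc <- unique(cp$lnc)
  decoy_lnc <- head(setdiff(co$truth$de_genes$gene_id, coupled_lnc), 10)
  expect_gt(length(decoy_lnc), 0)
  pc <- co$annotation$gene_id[co$annotation$biotype == "protein_coding"]
  pt <- partner_sets(lgt, c(coupled_lnc, decoy_lnc), pc)
  # most module genes are flagged partners of their coupled lncRNA
  pair1 <- cp[1, ]
  mod_genes <- co$gene_sets[[pair1$collection]][[pair1$set]]
  flagged <- pt$significant[pt$lnc == pair1$lnc & pt$partner %in% mod_genes]
  expect_gt(mean(flagged), 0.8)
  en <- suppressMessages(enrich_all(pt, co$gene_sets))
  planted <- dplyr::semi_join(en, cp, by = c(lnc = "lnc", feature = "set"))
  expect_true(all(planted$enriched))
  decoys <- dplyr::filter(en, .data$lnc %in% decoy_lnc, .data$feature %in% cp$set)
  expect_false(any(decoys$enriched))
  # enrichment gate consistency
  flagged_en <- dplyr::filter(en, .data$enriched)
  expect_true(all(flagged_en$or > 1 & flagged_en$fdr < 0.05))
})

test_that("adding never-significant decoy genes outside all features cannot shrink OR", {
  set.seed(20)
  u <- sprintf("g%03d", 1:100)
  feat <- u[1:20]
  partners <- u[c(1:10, 40:44)]
  tab1 <- build_contingency(feat, partners, u)
  r1 <- enrichment_test(tab1)
  u2 <- c(u, sprintf("decoy%03d", 1:100)) # decoys: not partners, in no feature
  tab2 <- build_contingency(feat, partners, u2)
  expect_equal(tab2[["a"]], tab1[["a"]])
  expect_equal(tab2[["c"]], tab1[["c"]])
  r2 <- enrichment_test(tab2)
  expect_gte(r2$or, r1$or)
})

test_that("track correlations recover planted signature loadings with signs", {
  co <- simulate_cohort(sim_config(n_tumor = 120, n_normal = 10, n_lnc = 60,
                                   n_pc = 600, n_cell_types = 4, markers_per_type = 4,
                                   n_latent = 2, n_hallmark = 5, n_immune_process = 5,
                                   coupling_strength = 1.5, seed = 66))
  fpkm <- to_fpkm(co$counts, co$annotation)
  tum <- co$clinical$sample_id[co$clinical$condition == "tumor"]
  lgt <- as_expression_matrix(log2(unclass(fpkm)[, tum] + 1), "log2FPKM")
  sl <- co$truth$signature_loadings
  tracks <- t(co$signature_scores)
  tc <- correlate_tracks(lgt, unique(sl$lnc), tracks)
  got <- dplyr::inner_join(tc, sl, by = c(lnc = "lnc", track = "track"))
  expect_true(all(got$significant))
  expect_equal(sign(got$rs), got$sign)
  # a track equal to the lncRNA's own expression correlates perfectly
  self_track <- unclass(lgt)[sl$lnc[1], , drop = FALSE]
  rownames(self_track) <- "self"
  tc2 <- correlate_tracks(lgt, sl$lnc[1], self_track)
  expect_equal(tc2$rs, 1)
  # misaligned samples abort
  bad <- tracks; colnames(bad) <- paste0("x", seq_len(ncol(bad)))
  expect_error(correlate_tracks(lgt, sl$lnc[1], bad), "align")
})

test_that("mediation edges are significant feature partners ranked by |Rs|", {
  pt <- tibble::tibble(
    lnc = "L1", partner = sprintf("g%02d", 1:6),
    rs = c(0.9, -0.8, 0.5, 0.2, 0.95, 0.1),
    p = 1e-6, fdr = 1e-5,
    significant = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE))
  colls <- list(proc = list(F1 = c("g01", "g02", "g04", "g06"), F2 = "g05"))
  enr <- tibble::tibble(lnc = "L1", collection = "proc", feature = "F1",
                        enriched = TRUE)
  ed <- mediation_edges(pt, colls, enr, top_k = 5)
  expect_equal(ed$gene_id, c("g01", "g02")) # significant & in F1, |Rs| order
  expect_equal(ed$sign, c(1, -1))
  ed2 <- mediation_edges(pt, colls, enr, top_k = 1)
  expect_equal(nrow(ed2), 1)
  # edges are a subset of significant partners in the feature, by construction
  expect_true(all(ed$gene_id %in% intersect(pt$partner[pt$significant], colls$proc$F1)))
  # no enriched pairs -> empty edge table
  enr0 <- dplyr::mutate(enr, enriched = FALSE)
  expect_equal(nrow(mediation_edges(pt, colls, enr0)), 0)
})
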