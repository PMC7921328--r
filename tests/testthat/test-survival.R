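test_that("Cox beta matches a grid search of the hand-written partial likelihood", {
  set.seed(12)
  n <- 8
  x <- rnorm(n)
  time <- sort(rexp(n, 0.2)) # distinct times
  event <- rbinom(n, 1, 0.8); event[1] <- 1
  fit <- cox_univariate(x, time, event)
  grid <- seq(-4, 4, by = 1e-4)
  ll <- vapply(grid, oracle_cox_loglik, numeric(1), time = time, event = event, x = x)
  expect_equal(fit$beta, grid[which.max(ll)], tolerance = 1e-3)
})

test_that("Cox beta is translation-invariant and scale-equivariant", {
  set.seed(5)
  n <- 60
  x <- rnorm(n)
  time <- rexp(n, 0.1 * exp(0.5 * x))
  event <- rbinom(n, 1, 0.7)
  event[1:3] <- 1
  b0 <- cox_univariate(x, time, event)$beta
  expect_equal(cox_univariate(x + 7, time, event)$beta, b0, tolerance = 1e-6)
  expect_equal(cox_univariate(3 * x - 1, time, event)$beta, b0 / 3, tolerance = 1e-6)
})

test_that("Cox flags monotone-likelihood fits instead of returning garbage", {
  # perfect separation: the one event has the uniquely largest covariate
  x <- c(5, 0, 0, 0, 0, 0)
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 0, 0, 0, 0, 0)
  fit <- cox_univariate(x, time, event)
  expect_false(fit$converged)
  expect_true(is.infinite(fit$hr))
  expect_error(cox_univariate(x, time, rep(0, 6)), "one event")
})

test_that("median dichotomization applies the stated tie rule", {
  expect_equal(as.character(dichotomize_median(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  # ties at the median go low
  expect_equal(as.character(dichotomize_median(c(1, 2, 2, 3))),
               c("low", "low", "low", "high"))
  expect_error(dichotomize_median(rep(3, 5)), "constant")
  # partition property on random non-constant vectors
  set.seed(2)
  for (i in 1:20) {
    v <- sample(1:5, 11, replace = TRUE)
    if (length(unique(v)) < 2) next
    g <- dichotomize_median(v)
    expect_equal(length(g), 11)
    expect_true(all(table(g) > 0))
  }
})

test_that("KM estimator matches closed forms and a hand-computed censored table", {
  # no censoring, events at 1..4: survival steps 0.75, 0.5, 0.25, 0
  km <- km_estimate(1:4, rep(1, 4))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  # all censored: S = 1 everywhere
  km2 <- km_estimate(1:5, rep(0, 5))
  expect_true(all(km2$surv == 1))
  # mixed censoring, n = 8, hand product-limit:
  # times 1+ 2 2 3+ 4 5+ 6 7 ; events at 2 (d=2,n=7), 4 (d=1,n=4), 6 (d=1,n=2), 7 (d=1,n=1)
  time <- c(1, 2, 2, 3, 4, 5, 6, 7)
  event <- c(0, 1, 1, 0, 1, 0, 1, 1)
  km3 <- km_estimate(time, event)
  hand <- cumprod(c(1 - 2 / 7, 1 - 1 / 4, 1 - 1 / 2, 1 - 1 / 1))
  expect_equal(km3$surv[km3$n_event > 0], hand)
  # with no censoring, KM equals 1 - empirical CDF at the event times
  set.seed(7)
  t2 <- sort(sample(1:100, 12))
  km4 <- km_estimate(t2, rep(1, 12))
  expect_equal(km4$surv, 1 - seq_len(12) / 12)
})

test_that("log-rank statistic matches the hand formula and is label-symmetric", {
  set.seed(8)
  n <- 30
  time <- rexp(n, 0.1); event <- rbinom(n, 1, 0.7); grp <- rep(c("a", "b"), 15)
  res <- logrank_test(grp, time, event)
  expect_equal(res$chisq, oracle_logrank_chisq(time, event, grp), tolerance = 1e-8)
  swapped <- logrank_test(ifelse(grp == "a", "b", "a"), time, event)
  expect_equal(res$chisq, swapped$chisq)
  expect_error(logrank_test(rep("a", n), time, event), "two")
})

test_that("the prognostic screen recovers planted hazardous lncRNAs", {
  co <- simulate_cohort(sim_config(n_tumor = 150, n_normal = 10, n_lnc = 80,
                                   n_pc = 600, n_cell_types = 4, markers_per_type = 4,
                                   n_latent = 1, n_hallmark = 5, n_immune_process = 5,
                                   n_prognostic = 5, surv_beta = 0.8, seed = 33))
  fpkm <- to_fpkm(co$counts, co$annotation)
  scr <- prognostic_screen(fpkm, co$truth$de_genes$gene_id, co$clinical, "os",
                           min_expr = -1)
  tab <- tidy(scr)
  tr <- co$truth$prognostic_genes
  hit <- tab$label[match(tr$gene_id, tab$gene_id)]
  expect_gte(sum(hit == "bad", na.rm = TRUE), 4)
  # disease-free endpoint also runs
  scr2 <- prognostic_screen(fpkm, co$truth$de_genes$gene_id, co$clinical, "dfs",
                            min_expr = -1)
  expect_gt(nrow(tidy(scr2)), 0)
})

test_that("a planted protective lncRNA is never labeled bad", {
  labels <- purrr::map_chr(1:15, function(s) {
    co <- simulate_cohort(sim_config(n_tumor = 100, n_normal = 10, n_lnc = 40,
                                     n_pc = 500, n_cell_types = 4, markers_per_type = 4,
                                     n_latent = 1, n_hallmark = 5, n_immune_process = 5,
                                     n_prognostic = 1, surv_beta = 0.8,
                                     prognostic_signs = -1, seed = 200 + s))
    fpkm <- to_fpkm(co$counts, co$annotation)
    g <- co$truth$prognostic_genes$gene_id
    scr <- tidy(prognostic_screen(fpkm, g, co$clinical, "os", min_expr = -1))
    scr$label[scr$gene_id == g]
  })
  expect_false(any(labels == "bad"))
})

test_that("screening an empty candidate list warns and returns an empty table", {
  co <- simulate_cohort(sim_config(n_tumor = 20, n_normal = 5, n_lnc = 40,
                                   n_pc = 500, n_cell_types = 4, markers_per_type = 4,
                                   n_latent = 1, n_hallmark = 5, n_immune_process = 5,
                                   seed = 3))
  fpkm <- to_fpkm(co$counts, co$annotation)
  expect_warning(
    scr <- prognostic_screen(fpkm, co$truth$de_genes$gene_id[1],
                             co$clinical, "os", min_expr = 1e9),
    "filter")
  expect_equal(nrow(tidy(scr)), 0)
})
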