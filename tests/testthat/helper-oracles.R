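# Independent reference implementations used as oracles. These deliberately
# use brute-force formulations (explicit loops, closed forms, enumeration)
# and never call the package functions they check.

# Benjamini-Hochberg by sort / scale / cummin / unsort
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# upper-tail hypergeometric P(X >= a) by direct enumeration with choose()
oracle_hyper_p <- function(a, b, cc, d) {
  n <- a + b + cc + d
  draws <- a + b
  white <- a + cc
  ks <- max(0, draws - (n - white)):min(draws, white)
  probs <- choose(white, ks) * choose(n - white, draws - ks) / choose(n, draws)
  sum(probs[ks >= a])
}

# two-group log-rank chi-square from the O-E / V tables, written out by hand
oracle_logrank_chisq <- function(time, event, group) {
  g <- as.integer(as.factor(group)) # 1/2
  ev_times <- sort(unique(time[event == 1]))
  OE <- 0; V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1L)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g == 1L)
    OE <- OE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  OE^2 / V
}

# Spearman rho via hand-counted average ranks and the explicit Pearson formula
oracle_spearman <- function(x, y) {
  hand_rank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  rx <- hand_rank(x); ry <- hand_rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# GSVA-style score by literal step-by-step enumeration: double-loop kernel
# CDF, explicit per-sample ordering, one walk step per gene
oracle_gsva <- function(m, set_genes, tau = 1) {
  n_gene <- nrow(m); n_samp <- ncol(m)
  z <- matrix(0, n_gene, n_samp)
  for (i in seq_len(n_gene)) {
    h <- max(sd(m[i, ]), 1e-6) / 4
    for (j in seq_len(n_samp)) {
      acc <- 0
      for (k in seq_len(n_samp)) acc <- acc + pnorm((m[i, j] - m[i, k]) / h)
      z[i, j] <- acc / n_samp
    }
  }
  in_set <- rownames(m) %in% set_genes
  m_size <- sum(in_set)
  out <- numeric(n_samp)
  for (j in seq_len(n_samp)) {
    ord <- order(z[, j], decreasing = TRUE)
    w <- abs(n_gene / 2 - seq_len(n_gene))^tau
    wsum <- sum(w[in_set[ord]])
    v <- 0; vmax <- 0; vmin <- 0
    for (step in seq_len(n_gene)) {
      if (in_set[ord[step]]) v <- v + w[step] / wsum
      else v <- v - 1 / (n_gene - m_size)
      vmax <- max(vmax, v); vmin <- min(vmin, v)
    }
    out[j] <- max(0, vmax) + min(0, vmin)
  }
  out
}

# Efron-tie Cox partial log-likelihood, written from the definition, for
# grid-search maximization
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    sum_r <- sum(exp(beta * x[R]))
    sum_d <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum_r - l / d * sum_d)
    }
  }
  ll
}

# small deterministic count fixture
tiny_counts <- function(n_gene = 30, n_samp = 10, seed = 42) {
  set.seed(seed)
  m <- matrix(rnbinom(n_gene * n_samp, mu = 50, size = 5), n_gene, n_samp,
              dimnames = list(sprintf("g%03d", seq_len(n_gene)),
                              sprintf("s%02d", seq_len(n_samp))))
  as_expression_matrix(m, "counts")
}

# binomial 99% half-width around a nominal rate
binom99_halfwidth <- function(nominal, n) qnorm(0.995) * sqrt(nominal * (1 - nominal) / n)
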