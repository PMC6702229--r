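# Shared fixtures, built lazily once per test file.

.fx <- new.env(parent = emptyenv())

# A small but structured cohort: 3 clusters + supra, both omic blocks.
fx_cohort <- function() {
  if (is.null(.fx$cohort))
    .fx$cohort <- generate_cohort(sim_config(
      n_samples = 60, cluster_sizes = c(A = 22, B = 20, C = 14),
      n_supra = 4, n_intermediate = 0, n_genes = 300, n_cpgs = 250,
      seed = 11))
  .fx$cohort
}

fx_truth <- function() {
  co <- fx_cohort()
  stats::setNames(co$truth$cluster, co$truth$sample_id)
}

# Analysis-scale blocks from the fixture cohort.
fx_blocks <- function() {
  if (is.null(.fx$blocks)) {
    co <- fx_cohort()
    counts <- drop_sex_chromosome_features(filter_low_expression(co$expression),
                                           co$annotation)
    en <- normalize_expression(counts)
    mv <- beta_to_m(clamp_beta(co$methylation))
    .fx$blocks <- list(
      expression = en[select_variable_features(en, 0.5), , drop = FALSE],
      methylation = mv[select_variable_features(mv, 0.05), , drop = FALSE])
  }
  .fx$blocks
}

# Noiseless rank-2 two-block data with centred planted scores.
fx_rank2_blocks <- function(n = 24, p1 = 30, p2 = 20, seed = 4) {
  set.seed(seed)
  Z0 <- matrix(rnorm(n * 2), n, 2)
  Z0 <- scale(Z0, scale = FALSE)            # column-centred scores
  W1 <- matrix(rnorm(p1 * 2), p1, 2)
  W2 <- matrix(rnorm(p2 * 2), p2, 2)
  samples <- sprintf("s%02d", seq_len(n))
  X1 <- W1 %*% t(Z0); dimnames(X1) <- list(sprintf("f%03d", 1:p1), samples)
  X2 <- W2 %*% t(Z0); dimnames(X2) <- list(sprintf("m%03d", 1:p2), samples)
  list(blocks = list(b1 = X1, b2 = X2), Z = Z0, W1 = W1, W2 = W2)
}

# A mock factor model with chosen scores / variance-explained table.
fx_mock_model <- function(Z, varexp) {
  K <- ncol(Z)
  if (is.null(rownames(Z))) rownames(Z) <- sprintf("s%03d", seq_len(nrow(Z)))
  colnames(Z) <- paste0("LF", seq_len(K))
  W <- matrix(1 / sqrt(10), 10, K,
              dimnames = list(sprintf("f%02d", 1:10), colnames(Z)))
  colnames(varexp) <- colnames(Z)
  structure(list(Z = Z, W = list(block = W), varexp = varexp,
                 d = rep(1, K), converged = TRUE, iterations = 1),
            class = "factor_model")
}

# Textbook Benjamini-Hochberg, written independently of p.adjust.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Two-sided Fisher exact p by hypergeometric enumeration (point-probability
# rule), independent of stats::fisher.test.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n_ <- c + d; k <- a + c
  lo <- max(0, k - n_); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Signed standardized logrank statistic, computed from first principles.
logrank_oracle <- function(times, events, grp2) {
  ts <- sort(unique(times[events == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    at_risk <- times >= t
    n_tot <- sum(at_risk); n2 <- sum(at_risk & grp2)
    d_tot <- sum(times == t & events == 1)
    d2 <- sum(times == t & events == 1 & grp2)
    O <- O + d2
    E <- E + d_tot * n2 / n_tot
    if (n_tot > 1)
      V <- V + d_tot * (n2 / n_tot) * (1 - n2 / n_tot) *
        (n_tot - d_tot) / (n_tot - 1)
  }
  (O - E) / sqrt(V)
}
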