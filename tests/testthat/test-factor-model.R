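test_that("with no missing samples the fit equals the truncated-SVD oracle", {
  set.seed(5)
  samples <- sprintf("s%02d", 1:20)
  b1 <- matrix(rnorm(40 * 20), 40, 20,
               dimnames = list(sprintf("f%03d", 1:40), samples))
  b2 <- matrix(rnorm(25 * 20), 25, 20,
               dimnames = list(sprintf("m%03d", 1:25), samples))
  blocks <- list(b1 = b1, b2 = b2)
  fit <- fit_joint_factors(blocks, K = 3)
  expect_true(fit$converged)
  expect_equal(fit$iterations, 1)

  prep <- nenstrat:::prepare_blocks(blocks)
  sv <- svd(prep$X, nu = 3, nv = 3)
  # reconstruction is unique; factors match up to sign
  recon_fit <- rbind(fit$W$b1, fit$W$b2) %*% t(fit$Z)
  recon_or <- sv$u %*% (sv$d[1:3] * t(sv$v))
  expect_lt(max(abs(recon_fit - recon_or)), 1e-8)
  Z_or <- sv$v %*% diag(sv$d[1:3])
  for (k in 1:3)
    expect_lt(min(max(abs(fit$Z[, k] - Z_or[, k])),
                  max(abs(fit$Z[, k] + Z_or[, k]))), 1e-8)
  # sign convention: the largest-magnitude stacked loading is positive
  W <- rbind(fit$W$b1, fit$W$b2)
  for (k in 1:3) expect_gt(W[which.max(abs(W[, k])), k], 0)
})

test_that("exact rank-1 data give variance explained of 1", {
  set.seed(6)
  w <- rnorm(15); z <- scale(rnorm(10), scale = FALSE)[, 1]
  X <- w %*% t(z)
  dimnames(X) <- list(sprintf("f%02d", 1:15), sprintf("s%02d", 1:10))
  fit <- fit_joint_factors(list(b = X), K = 1)
  expect_equal(unname(fit$varexp[1, 1]), 1, tolerance = 1e-10)
  expect_equal(variance_explained(fit), fit$varexp)
})

test_that("a sample missing one block is recovered from the other", {
  # noiseless rank-2 data; the held-out sample's scores are zero so that
  # per-block feature centring is unaffected by dropping its column
  set.seed(4)
  n <- 24
  Z0 <- matrix(rnorm(n * 2), n, 2)
  Z0[-7, ] <- scale(Z0[-7, ], scale = FALSE)
  Z0[7, ] <- 0
  W1 <- matrix(rnorm(30 * 2), 30, 2)
  W2 <- matrix(rnorm(20 * 2), 20, 2)
  samples <- sprintf("s%02d", seq_len(n))
  b1 <- W1 %*% t(Z0); dimnames(b1) <- list(sprintf("f%03d", 1:30), samples)
  b2 <- W2 %*% t(Z0); dimnames(b2) <- list(sprintf("m%03d", 1:20), samples)
  d <- list(blocks = list(b1 = b1, b2 = b2), Z = Z0)
  blocks <- d$blocks
  # drop sample 7 from block 2 entirely
  blocks$b2 <- blocks$b2[, -7]
  fit <- fit_joint_factors(blocks, K = 2, tol = 1e-12, obj_tol = 1e-14,
                           max_iter = 5000)
  # oracle: least-squares projection of the sample's observed block-1 data
  # onto the fitted block-1 loadings
  prep <- nenstrat:::prepare_blocks(blocks)
  x1 <- prep$X[seq_len(nrow(blocks$b1)), 7]
  z_oracle <- solve(crossprod(fit$W$b1), crossprod(fit$W$b1, x1))
  expect_lt(max(abs(fit$Z[7, ] - z_oracle)), 1e-6)
  # and the fitted scores span the planted factor subspace (the SVD may
  # rotate within it, so compare subspaces, not columns)
  qf <- qr.Q(qr(fit$Z))
  qt <- qr.Q(qr(d$Z))
  expect_lt(max(acos(pmin(1, svd(crossprod(qf, qt))$d))), 1e-5)
})

test_that("variance explained matches the residual sum-of-squares oracle", {
  set.seed(9)
  samples <- sprintf("s%02d", 1:12)
  X <- matrix(rnorm(30 * 12), 30, 12,
              dimnames = list(sprintf("f%02d", 1:30), samples))
  fit <- fit_joint_factors(list(b = X), K = 4)
  prep <- nenstrat:::prepare_blocks(list(b = X))
  tot <- sum(prep$X^2)
  # orthogonal factors: per-factor fractions add, so the cumulative sum
  # equals 1 - RSS/TSS of the rank-k reconstruction
  for (k in 1:4) {
    recon <- fit$W$b[, 1:k, drop = FALSE] %*% t(fit$Z[, 1:k, drop = FALSE])
    oracle <- 1 - sum((prep$X - recon)^2) / tot
    expect_equal(sum(fit$varexp[1, 1:k]), oracle, tolerance = 1e-10)
  }
  # full-rank case: varexp sums to 1
  fit_full <- fit_joint_factors(list(b = X), K = 11)
  expect_equal(sum(fit_full$varexp), 1, tolerance = 1e-8)
  # invariance to sample permutation
  perm <- sample(ncol(X))
  fit_p <- fit_joint_factors(list(b = X[, perm]), K = 4)
  expect_equal(fit_p$varexp, fit$varexp, tolerance = 1e-8)
})

test_that("factor retention applies the 2% in-at-least-one-block rule", {
  Z <- matrix(rnorm(40), 10, 4)
  ve <- rbind(c(0.30, 0.10, 0.019, 0.019),
              c(0.25, 0.02, 0.021, 0.018))
  m <- fx_mock_model(Z, ve)
  kept <- select_factors(m)
  expect_identical(colnames(kept$Z), c("LF1", "LF2", "LF3"))  # (.019,.021) kept
  expect_identical(ncol(select_factors(m, 0)$Z), 4L)          # identity
  expect_error(select_factors(m, 0.5), "empty model")
})

test_that("factor stability is exact for deterministic fits and orthogonal factors", {
  d <- fx_rank2_blocks()
  st <- factor_stability(d$blocks, K = 2, n_runs = 3, seed = 2)
  expect_true(all(abs(st$matched - 1) < 1e-6))
  expect_equal(unname(diag(st$cross)), c(1, 1))
  # cross-factor correlation near zero for orthogonal planted factors
  expect_lt(abs(st$cross[1, 2]), 0.2)
  # summary symmetric with unit diagonal
  expect_equal(st$matched[, , 1], t(st$matched[, , 1]))
  expect_true(all(abs(diag(st$matched[, , 1]) - 1) < 1e-12))
})

test_that("covariate association flags a planted coding and controls type I", {
  set.seed(3)
  n <- 60
  clin <- data.frame(sample_id = sprintf("s%03d", 1:n),
                     sex = sample(c("M", "F"), n, TRUE),
                     smoking = sample(c("never", "former"), n, TRUE),
                     stage = sample(c("I", "II"), n, TRUE))
  Z <- cbind(ifelse(clin$sex == "M", 1, 0) * 3 + rnorm(n, sd = 0.1),
             rnorm(n))
  rownames(Z) <- clin$sample_id
  m <- fx_mock_model(Z, rbind(c(0.5, 0.1)))
  res <- associate_factors_with_covariates(m, clin, c("sex", "smoking", "stage"))
  sex1 <- res[res$factor == "LF1" & res$term == "sex", ]
  expect_identical(nrow(sex1), 1L)
  expect_lt(sex1$q[1], 1e-10)
  # BH equals the textbook oracle on the raw p list
  expect_equal(res$q, bh_oracle(res$p), tolerance = 1e-12)
  # type I: pure-noise factors are rarely flagged
  set.seed(4)
  flags <- replicate(300, {
    Zn <- matrix(rnorm(n), ncol = 1, dimnames = list(clin$sample_id, NULL))
    mn <- fx_mock_model(Zn, rbind(0.1))
    r <- associate_factors_with_covariates(mn, clin,
                                           c("sex", "smoking", "stage"))
    mean(r$significant)
  })
  expect_lte(mean(flags), 0.05)
})

test_that("mutation association honours the recurrence threshold", {
  set.seed(8)
  n <- 50
  Z <- matrix(rnorm(n * 2), n, 2,
              dimnames = list(sprintf("s%03d", 1:n), NULL))
  top <- order(Z[, 1], decreasing = TRUE)[1:6]
  mut <- matrix(0L, 3, n,
                dimnames = list(c("planted", "rare", "flat"), rownames(Z)))
  mut["planted", top] <- 1L                      # aligned with factor 1
  mut["rare", 1:2] <- 1L                         # below threshold of 3
  mut["flat", sample(n, 8)] <- 1L
  m <- fx_mock_model(Z, rbind(c(0.4, 0.2)))
  res <- associate_factors_with_mutations(m, mut, min_recurrence = 3)
  expect_false("rare" %in% res$gene)
  planted1 <- res[res$gene == "planted" & res$factor == "LF1", ]
  expect_lt(planted1$q, 0.01)
  # permuted mutation labels give uniform p-values
  set.seed(9)
  ps <- replicate(500, {
    mp <- mut["flat", sample(n), drop = FALSE]
    colnames(mp) <- rownames(Z)
    associate_factors_with_mutations(m, mp)$p[1]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("loading-set enrichment detects heavy-loading sets and skips degenerate ones", {
  set.seed(10)
  W <- matrix(rnorm(200, sd = 0.05), 200, 2)
  heavy <- 1:15
  W[heavy, 1] <- rnorm(15, mean = 2)
  rownames(W) <- sprintf("g%03d", 1:200)
  colnames(W) <- c("LF1", "LF2")
  m <- structure(list(Z = matrix(0, 5, 2), W = list(expr = W),
                      varexp = rbind(c(0.5, 0.2))), class = "factor_model")
  sets <- list(planted = rownames(W)[heavy],
               disjoint = c("absent1", "absent2"))
  expect_message(res <- loading_set_enrichment(m, sets), "skipped")
  expect_lt(res$q[res$set == "planted" & res$factor == "LF1"], 0.05)
  expect_false("disjoint" %in% res$set)
  # random sets are rarely significant
  set.seed(11)
  qs <- replicate(100, {
    s <- list(rand = sample(rownames(W), 15))
    min(loading_set_enrichment(m, s)$q)
  })
  expect_gte(mean(qs >= 0.05), 0.9)
})

test_that("reconstruction objective is non-increasing across EM iterations", {
  d <- fx_rank2_blocks(n = 20, p1 = 25, p2 = 15, seed = 13)
  blocks <- d$blocks
  blocks$b1 <- blocks$b1 + matrix(rnorm(length(blocks$b1), sd = 0.3),
                                  nrow(blocks$b1))
  blocks$b2 <- blocks$b2[, -c(3, 11)]
  fit <- suppressWarnings(fit_joint_factors(blocks, K = 3, obj_tol = 1e-9))
  expect_gte(length(fit$objective), 2)
  expect_true(all(diff(fit$objective) <= 1e-10))
})

test_that("fitted factors recover the planted cluster-factor subspace", {
  # noiseless data: recovery is exact
  d <- fx_rank2_blocks()
  fit0 <- fit_joint_factors(d$blocks, K = 2)
  q0f <- qr.Q(qr(fit0$Z)); q0t <- qr.Q(qr(d$Z))
  expect_lt(max(acos(pmin(1, svd(crossprod(q0f, q0t))$d))) * 180 / pi, 0.01)

  # at the generator's default noise the cluster-bearing factor subspace is
  # recovered to within the measurement floor set by the number of
  # informative features (regression bound; see the methods vignette for the
  # measured recovery quality)
  co <- generate_cohort(sim_config(seed = 7))
  counts <- drop_sex_chromosome_features(filter_low_expression(co$expression),
                                         co$annotation)
  counts <- counts[!grepl("^IMM_", rownames(counts)), ]  # non-factor structure
  en <- normalize_expression(counts)
  mv <- beta_to_m(clamp_beta(co$methylation))
  blocks <- list(expression = en[select_variable_features(en, 0.5), ],
                 methylation = mv[select_variable_features(mv, 0.05), ])
  fit <- suppressWarnings(fit_joint_factors(blocks, K = 5))
  Zt <- as.matrix(co$truth[, paste0("LF", 1:2)])
  rownames(Zt) <- co$truth$sample_id
  Zf <- fit$Z[rownames(Zt), 1:2]
  qf <- qr.Q(qr(scale(Zf, scale = FALSE)))
  qt <- qr.Q(qr(scale(Zt, scale = FALSE)))
  angles <- acos(pmin(1, svd(crossprod(qf, qt))$d)) * 180 / pi
  expect_lt(max(angles), 15)
})

test_that("K outside the admissible range is rejected", {
  d <- fx_rank2_blocks(n = 10, p1 = 8, p2 = 6)
  expect_error(fit_joint_factors(d$blocks, K = 10), "K must be below")
})
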