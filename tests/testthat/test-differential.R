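make_groups_matrix <- function(n_feat = 40, n_per = 8, delta = 0, seed = 1) {
  set.seed(seed)
  g <- factor(rep(c("A", "B"), each = n_per))
  m <- matrix(rnorm(n_feat * 2 * n_per), n_feat,
              dimnames = list(sprintf("f%03d", seq_len(n_feat)),
                              sprintf("s%02d", seq_len(2 * n_per))))
  m[, g == "A"] <- m[, g == "A"] + delta
  list(m = m, g = g)
}

test_that("d0 = 0 with theta = 0 reduces to the classical two-sample t", {
  d <- make_groups_matrix(delta = 0.5)
  res <- fit_moderated_pairwise(d$m, d$g, theta = 0, d0 = 0)[["A_vs_B"]]
  oracle <- apply(d$m, 1, function(x) {
    tt <- stats::t.test(x[d$g == "A"], x[d$g == "B"], var.equal = TRUE)
    c(t = unname(tt$statistic), p = tt$p.value, b = unname(diff(rev(tt$estimate))))
  })
  expect_equal(res$t, unname(oracle["t", ]), tolerance = 1e-10)
  expect_equal(res$p, unname(oracle["p", ]), tolerance = 1e-10)
  expect_equal(res$b, unname(oracle["b", ]), tolerance = 1e-10)
  expect_equal(res$df[1], 14)
})

test_that("the threshold null uses max(|b| - theta, 0) in the numerator", {
  d <- make_groups_matrix(delta = 3, seed = 2)
  res <- fit_moderated_pairwise(d$m, d$g, theta = 2, d0 = 0)[["A_vs_B"]]
  expect_equal(abs(res$t), pmax(abs(res$b) - 2, 0) / res$se, tolerance = 1e-12)
  # |b| <= theta gives statistic 0 and p = 1
  small <- abs(res$b) <= 2
  expect_true(any(small))
  expect_true(all(res$t[small] == 0))
  expect_true(all(res$p[small] == 1))
})

test_that("moderation limits behave as specified", {
  d <- make_groups_matrix(seed = 3)
  # d0 = Inf: every feature shares the prior variance
  res_inf <- fit_moderated_pairwise(d$m, d$g, d0 = Inf, s0_sq = 0.7)[["A_vs_B"]]
  expect_equal(stats::var(res_inf$se), 0, tolerance = 1e-20)
  prior <- attr(fit_moderated_pairwise(d$m, d$g, d0 = Inf, s0_sq = 0.7),
                "prior")
  expect_identical(prior$d0, Inf)
  # estimated prior lies strictly between the limits and moderated variances
  # are a convex combination of feature and prior variance
  fitted <- fit_moderated_pairwise(d$m, d$g)
  prior2 <- attr(fitted, "prior")
  expect_gt(prior2$d0, 0)
  expect_gt(prior2$s0_sq, 0)
  res0 <- fit_moderated_pairwise(d$m, d$g, d0 = 0)[["A_vs_B"]]
  res_p <- fit_moderated_pairwise(d$m, d$g, d0 = Inf,
                                  s0_sq = prior2$s0_sq)[["A_vs_B"]]
  res <- fitted[["A_vs_B"]]
  # moderated variance is a convex combination of the feature variance and
  # the prior variance, so it lies between them
  r_feat <- res$se^2 / res0$se^2
  r_prior <- res_p$se^2 / res0$se^2
  expect_true(all((r_feat - 1) * (r_feat - r_prior) <= 1e-10))
})

test_that("moderated statistics agree with the limma reference", {
  skip_if_not_installed("limma")
  d <- make_groups_matrix(n_feat = 120, delta = 0.8, seed = 4)
  res <- fit_moderated_pairwise(d$m, d$g, theta = 0)[["A_vs_B"]]
  design <- stats::model.matrix(~ d$g)
  efit <- limma::eBayes(limma::lmFit(d$m, design))
  expect_equal(attr(fit_moderated_pairwise(d$m, d$g), "prior")$d0,
               efit$df.prior, tolerance = 1e-6)
  # limma's coefficient is B - A on this coding; ours is A - B
  expect_equal(res$t, unname(-efit$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p, unname(efit$p.value[, 2]), tolerance = 1e-8)
})

test_that("null simulations keep the BH false-discovery fraction at bay", {
  set.seed(5)
  fractions <- replicate(20, {
    d <- make_groups_matrix(n_feat = 2000, n_per = 10,
                            seed = sample.int(1e6, 1))
    res <- fit_moderated_pairwise(d$m, d$g)[["A_vs_B"]]
    mean(res$q < 0.05)
  })
  expect_lte(mean(fractions), 0.05)
})

test_that("significant sets shrink monotonically in the threshold", {
  d <- make_groups_matrix(n_feat = 300, delta = 1.5, seed = 6)
  sets <- lapply(c(0, 0.5, 1, 2), function(th) {
    r <- fit_moderated_pairwise(d$m, d$g, theta = th)[["A_vs_B"]]
    r$feature[r$q < 0.05]
  })
  for (i in seq_along(sets)[-1])
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("BH adjustment matches the textbook oracle and covariables enter the design", {
  d <- make_groups_matrix(seed = 7)
  covars <- data.frame(sex = rep(c("M", "F"), 8),
                       age = rnorm(16))
  res <- fit_moderated_pairwise(d$m, d$g, covariables = covars)[["A_vs_B"]]
  expect_equal(res$q, bh_oracle(res$p), tolerance = 1e-12)
  expect_equal(res$df[1], attr(fit_moderated_pairwise(d$m, d$g,
                                                      covariables = covars),
                               "prior")$d0 + (16 - 4))
  # groups with fewer than two samples are skipped with a warning
  g3 <- factor(c(as.character(d$g)[-1], "rare"), levels = c("A", "B", "rare"))
  expect_warning(fit_moderated_pairwise(d$m, g3), "skipped")
})

test_that("core features are directional intersections over focal pairs", {
  mk <- function(features, q, b) data.frame(feature = features, b = b,
                                            se = 1, t = b, df = 10,
                                            p = q, q = q)
  res <- structure(list(
    A_vs_B = mk(c("g1", "g2", "g3"), c(0.01, 0.01, 0.5), c(2, 2, 2)),
    A_vs_C = mk(c("g1", "g2", "g3"), c(0.5, 0.01, 0.01), c(2, 2, 2)),
    B_vs_C = mk(c("g1", "g2", "g3"), c(0.01, 0.01, 0.01), c(2, 2, 2))),
    class = "diff_result", theta = 0)
  expect_identical(core_features(res, "A"), "g2")
  # direction consistency: flip one pair's sign for g2
  res$A_vs_C$b[2] <- -2
  expect_identical(core_features(res, "A"), character(0))
  expect_identical(core_features(res, "A", require_direction = FALSE), "g2")
  # empty pairwise set gives an empty core
  res$A_vs_B$q[] <- 0.9
  expect_identical(core_features(res, "A", require_direction = FALSE),
                   character(0))
  expect_error(core_features(res, "Z"), "no pairwise result")
})

test_that("core genes of a planted cluster are recovered and mostly focal-specific", {
  co <- fx_cohort()
  truth <- fx_truth()
  counts <- drop_sex_chromosome_features(filter_low_expression(co$expression),
                                         co$annotation)
  en <- normalize_expression(counts)
  g <- truth[colnames(en)]
  de <- fit_moderated_pairwise(en, g, theta = 1)
  core_c <- core_features(de, "C")
  expect_gt(length(core_c), 5)
  # core set is almost exclusively a subset of the focal-vs-rest DE set
  rest <- fit_moderated_pairwise(en, factor(ifelse(g == "C", "C", "rest")),
                                 theta = 1)[["C_vs_rest"]]
  deg_rest <- rest$feature[rest$q < 0.05]
  expect_gte(mean(core_c %in% deg_rest), 0.9)
})

test_that("CpG-promoter mapping respects the window boundary on both sides", {
  tss <- data.frame(feature = c("gene1", "gene2"),
                    chrom = c("chr1", "chr2"), pos = c(10000L, 5000L))
  cpg <- data.frame(feature = c("cg1", "cg2", "cg3", "cg4", "cg5"),
                    chrom = c("chr1", "chr1", "chr1", "chr2", "chr3"),
                    pos = c(12000L, 12001L, 8000L, 5000L, 5000L))
  map <- map_cpgs_to_promoters(cpg, tss, window = 2000)
  expect_true(any(map$cpg == "cg1" & map$gene == "gene1"))   # exactly 2000
  expect_false("cg2" %in% map$cpg)                           # 2001: out
  expect_true(any(map$cpg == "cg3" & map$gene == "gene1"))   # -2000
  expect_true(any(map$cpg == "cg4" & map$gene == "gene2"))
  expect_false("cg5" %in% map$cpg)                           # chrom mismatch
  # brute-force all-pairs oracle
  set.seed(8)
  cpg_r <- data.frame(feature = sprintf("cg%02d", 1:40),
                      chrom = sample(c("chr1", "chr2"), 40, TRUE),
                      pos = sample.int(50000, 40))
  tss_r <- data.frame(feature = sprintf("g%02d", 1:15),
                      chrom = sample(c("chr1", "chr2"), 15, TRUE),
                      pos = sample.int(50000, 15))
  map_r <- map_cpgs_to_promoters(cpg_r, tss_r, window = 3000)
  oracle <- do.call(rbind, lapply(seq_len(nrow(cpg_r)), function(i)
    do.call(rbind, lapply(seq_len(nrow(tss_r)), function(j) {
      if (cpg_r$chrom[i] == tss_r$chrom[j] &&
          abs(cpg_r$pos[i] - tss_r$pos[j]) <= 3000)
        data.frame(cpg = cpg_r$feature[i], gene = tss_r$feature[j])
    }))))
  got <- paste(map_r$cpg, map_r$gene)
  expect_setequal(got, paste(oracle$cpg, oracle$gene))
})

test_that("methylation-expression correlation applies all three filters", {
  set.seed(9)
  n <- 30
  samples <- sprintf("s%02d", 1:n)
  driver <- runif(n, 0.1, 0.9)                     # wide IQR
  narrow <- 0.5 + runif(n, -0.05, 0.05)            # IQR below 0.25
  beta <- rbind(cg_drive = driver, cg_narrow = narrow,
                cg_null = runif(n, 0.2, 0.8))
  colnames(beta) <- samples
  expr <- rbind(geneA = 10 - 8 * driver + rnorm(n, sd = 0.3),
                geneB = 10 - 8 * narrow + rnorm(n, sd = 0.01),
                geneC = rnorm(n))
  colnames(expr) <- samples
  mapping <- data.frame(cpg = c("cg_drive", "cg_narrow", "cg_null"),
                        gene = c("geneA", "geneB", "geneC"))
  res <- expr_meth_correlation(expr, beta, mapping)
  expect_identical(res$gene, "geneA")
  expect_identical(res$direction, "negative")
  # Pearson oracle on a 5-point toy
  x5 <- c(0.1, 0.3, 0.5, 0.7, 0.9); y5 <- c(5, 4, 3.5, 2, 1)
  b5 <- matrix(x5, 1, dimnames = list("cg", paste0("t", 1:5)))
  e5 <- matrix(y5, 1, dimnames = list("g", paste0("t", 1:5)))
  r5 <- expr_meth_correlation(e5, b5,
                              data.frame(cpg = "cg", gene = "g"),
                              q_max = 1, r2_min = 0, iqr_min = 0)
  expect_equal(r5$r, cor(x5, y5), tolerance = 1e-12)
})

test_that("planted methylation-driven genes are recovered with negative direction", {
  co <- fx_cohort()
  counts <- filter_low_expression(co$expression)
  en <- normalize_expression(counts)
  ann <- co$annotation
  mapping <- map_cpgs_to_promoters(ann[ann$type == "cpg", ],
                                   ann[ann$type == "gene", ])
  res <- expr_meth_correlation(en, co$methylation, mapping)
  driven <- sprintf("g%04d", seq_len(co$config$n_methylation_driven_genes))
  expect_gt(nrow(res), 10)
  expect_true(all(res$gene %in% driven))
  expect_true(all(res$direction == "negative"))
  expect_true(all(res$q < 0.05 & res$r2 > 0.5 & res$iqr > 0.25))
  expect_false(any(duplicated(res$gene)))
})
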