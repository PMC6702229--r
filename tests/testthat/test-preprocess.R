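test_that("median-of-ratios size factors match hand computation", {
  m <- matrix(c(10, 20, 40,
                10, 20, 40), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- m; m2[, 2] <- 2 * m2[, 1]
  sf <- size_factors(m2)
  # geometric means are c_i * sqrt(2): factors 1/sqrt(2) and 2/sqrt(2)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  expect_equal(unname(sf[2] / sf[1]), 2)

  single <- m[, 1, drop = FALSE]
  expect_equal(unname(size_factors(single)), 1)

  allzero <- matrix(c(0, 5, 3, 0), 2)
  expect_error(size_factors(allzero), "no gene is positive")
})

test_that("expression normalisation is log2(count/sf + 1) and monotone", {
  m <- matrix(c(3, 0, 7, 1), 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  norm <- normalize_expression(m, size_factors = c(1, 1))
  expect_equal(norm["g1", "s1"], 2)       # log2(3 + 1)
  expect_equal(norm["g2", "s1"], 0)       # count 0 -> 0 at any size factor
  norm2 <- normalize_expression(m, size_factors = c(2, 2))
  expect_equal(norm2["g2", "s1"], 0)
  # monotone in counts for a fixed size factor
  x <- matrix(0:50, nrow = 1, dimnames = list("g", paste0("s", 0:50)))
  v <- normalize_expression(x, size_factors = rep(1.3, 51))
  expect_true(all(diff(v[1, ]) > 0))
  expect_error(normalize_expression(-m), "non-negative")
})

test_that("learned normalisation reproduces training values on a held-out copy", {
  co <- fx_cohort()
  counts <- co$expression
  model <- fit_normalization(counts, "expression")
  applied <- apply_normalization(model, counts)
  # training-time values: normalise, subset, centre/scale with model stats
  filtered <- filter_low_expression(counts)
  ref <- exp(rowMeans(log(filtered)))
  norm <- normalize_expression(filtered, reference = ref)
  manual <- (norm[model$selected, ] - model$centre) / model$scale
  expect_equal(applied, manual, tolerance = 1e-12)
  # a held-out sample identical to a training one gets identical values
  one <- counts[, 5, drop = FALSE]
  expect_equal(apply_normalization(model, one)[, 1], applied[, 5],
               tolerance = 1e-12)
})

test_that("low-expression filter keeps the CPM >= 1 in >= 2 samples boundary", {
  # 4 samples with library size 1e6 so counts are CPM directly
  lib <- 1e6
  m <- rbind(
    boundary = c(1, 1, 0, 0),      # CPM 1 in exactly 2 samples: kept
    once     = c(5, 0, 0, 0),      # only 1 sample: removed
    zeros    = c(0, 0, 0, 0),      # removed
    high     = c(10, 10, 10, 10))  # kept
  filler <- matrix(lib / 4, 4, 4,
                   dimnames = list(paste0("fill", 1:4), NULL))
  m <- rbind(m, sweep(filler, 2, colSums(m), "-"))
  colnames(m) <- paste0("s", 1:4)
  kept <- rownames(filter_low_expression(m))
  expect_true("boundary" %in% kept)
  expect_false("once" %in% kept)
  expect_false("zeros" %in% kept)
  expect_true("high" %in% kept)
  # brute-force oracle on a random toy matrix
  set.seed(1)
  toy <- matrix(rpois(5 * 6, 3), 5, 6,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  cpm <- sweep(toy, 2, colSums(toy), "/") * 1e6
  oracle <- rownames(toy)[rowSums(cpm >= 1) >= 2]
  expect_identical(rownames(filter_low_expression(toy)), oracle)
})

test_that("beta/M transforms are exact and guarded", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  b <- seq(0.001, 0.999, length.out = 200)
  expect_equal(m_to_beta(beta_to_m(b)), b, tolerance = 1e-12)
  expect_error(beta_to_m(c(0.2, 1)), "strictly")
  expect_error(beta_to_m(0), "strictly")
  expect_equal(clamp_beta(c(0, 1)), c(1e-6, 1 - 1e-6))
})

test_that("variance-fraction feature selection obeys its contract", {
  # variances 6, 3, 1 and one constant feature
  mk <- function(s) c(-s, 0, s)
  m <- rbind(a = mk(sqrt(6)), b = mk(sqrt(3)), c = mk(1), d = c(2, 2, 2))
  colnames(m) <- paste0("s", 1:3)
  expect_identical(select_variable_features(m, 0.5), "a")   # 6 >= 0.5 * 10
  expect_identical(sort(select_variable_features(m, 1)), c("a", "b", "c"))
  expect_false("d" %in% select_variable_features(m, 1))
  expect_error(select_variable_features(m, 0), "fraction")
  expect_error(select_variable_features(m, 1.2), "fraction")
  # nesting: selection at f1 <= f2 is a subset
  set.seed(2)
  big <- matrix(rnorm(50 * 8, sd = rep(runif(50, 0.2, 3), 8)), 50, 8,
                dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:8)))
  fr <- c(0.1, 0.3, 0.5, 0.8, 1)
  sels <- lapply(fr, function(f) select_variable_features(big, f))
  for (i in seq_along(fr)[-1])
    expect_true(all(sels[[i - 1]] %in% sels[[i]]))
})

test_that("sex-chromosome features are dropped by annotation", {
  ann <- data.frame(feature = paste0("g", 1:10),
                    chrom = c(rep("chr1", 8), "chrX", "chrY"))
  m <- matrix(1, 10, 3, dimnames = list(ann$feature, paste0("s", 1:3)))
  out <- drop_sex_chromosome_features(m, ann)
  expect_identical(rownames(out), setdiff(ann$feature, c("g9", "g10")))
  auto <- m[1:8, , drop = FALSE]
  expect_identical(drop_sex_chromosome_features(auto, ann), auto)
  expect_error(drop_sex_chromosome_features(
    matrix(1, 1, 1, dimnames = list("unknown", "s1")), ann), "annotation")
})

test_that("sex concordance flags exactly a planted swap", {
  co <- fx_cohort()
  clin <- co$clinical
  clin <- clin[clin$sample_id %in% colnames(co$expression), ]
  counts <- co$expression[, clin$sample_id]
  res <- sex_concordance_check(counts, clin, co$annotation)
  expect_identical(attr(res, "status"), "ok")
  expect_false(any(res$flag))
  # swap one label
  swapped <- clin
  swapped$sex[3] <- ifelse(swapped$sex[3] == "M", "F", "M")
  res2 <- sex_concordance_check(counts, swapped, co$annotation)
  expect_identical(res2$sample_id[res2$flag], clin$sample_id[3])
  # missing sex entry: reported unknown, not flagged
  nas <- clin; nas$sex[2] <- NA
  res3 <- sex_concordance_check(counts, nas, co$annotation)
  expect_identical(res3$reported[2], "unknown")
  expect_false(res3$flag[2])
  # no Y features: skipped with a warning status
  autosomal <- counts[!grepl("^gY", rownames(counts)), ]
  expect_warning(res4 <- sex_concordance_check(autosomal, clin, co$annotation),
                 "skipped")
  expect_identical(attr(res4, "status"), "skipped")
})
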