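# Inverse of the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)), used when moment-matching the variance prior.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Estimate the empirical-Bayes variance prior
#'
#' Moment matching on the log residual variances: under the hierarchical model
#' the log variances follow a scaled log-F, whose mean and variance involve
#' digamma/trigamma terms. Solving those identities gives the prior degrees of
#' freedom `d0` and prior variance `s0_sq`; when the observed spread of log
#' variances is no larger than expected from the residual degrees of freedom
#' alone, `d0 = Inf` (all features share one variance).
#'
#' @param s2 per-feature residual variances.
#' @param d residual degrees of freedom (scalar).
#' @return list with `s0_sq` and `d0`.
#' @export
estimate_moderation_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- stats::var(e)
  rhs <- evar - trigamma(d / 2)
  if (is.na(rhs) || rhs <= 0)
    return(list(s0_sq = exp(mean(e)), d0 = Inf))
  d0 <- 2 * trigamma_inverse(rhs)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(s0_sq = s0_sq, d0 = d0)
}

#' Pairwise moderated tests with a fold-change-threshold null
#'
#' Fits, per feature, one linear model `value ~ group + covariables`, then for
#' each group pair tests the null that the absolute group difference is below
#' `theta` using a moderated statistic: residual variances are shrunk towards
#' an empirical-Bayes prior, `s2_tilde = (d0 s0^2 + d s^2) / (d0 + d)`, and
#' the statistic is `t = sign(b) * max(|b| - theta, 0) / (s_tilde * c)` on
#' `d0 + d` degrees of freedom (`theta = 0` recovers the ordinary moderated
#' t; `d0 = 0` the classical per-feature t). BH adjustment is applied within
#' each pairwise family.
#'
#' @param mat feature x sample matrix of normalised values (log2 expression or
#'   M-values).
#' @param groups factor of group memberships aligned with columns.
#' @param covariables optional data frame of per-sample covariates.
#' @param theta effect-size threshold on the |b| scale (default 0; the
#'   expression analyses of this package use 2 on the log2 scale).
#' @param d0,s0_sq override the estimated prior (`d0 = 0` disables
#'   moderation; `d0 = Inf` pools all features to `s0_sq`).
#' @param pairs optional list of 2-vectors of group levels; default all pairs.
#' @return an object of class `diff_result`: a named list of per-pair data
#'   frames (feature, b, se, t, df, p, q) with the prior and theta attached.
#' @export
fit_moderated_pairwise <- function(mat, groups, covariables = NULL, theta = 0,
                                   d0 = NULL, s0_sq = NULL, pairs = NULL) {
  mat <- as.matrix(mat)
  groups <- factor(groups)
  if (theta < 0) stop("theta must be >= 0")
  if (length(groups) != ncol(mat)) stop("groups must align with columns")
  keep_lvl <- names(table(groups))[table(groups) >= 2]
  skipped <- setdiff(levels(groups), keep_lvl)
  if (length(skipped))
    warning("groups with <2 samples skipped: ", paste(skipped, collapse = ", "))
  use <- groups %in% keep_lvl
  mat <- mat[, use, drop = FALSE]
  groups <- droplevels(groups[use])
  dat <- data.frame(group = groups)
  if (!is.null(covariables)) {
    cov <- as.data.frame(covariables)[use, , drop = FALSE]
    for (j in seq_along(cov))
      if (is.character(cov[[j]])) cov[[j]] <- factor(cov[[j]])
    dat <- cbind(dat, cov)
  }
  X <- stats::model.matrix(~ ., data = dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    warning("collinear terms dropped: ", paste(drop, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  n <- nrow(X); pX <- ncol(X)
  d <- n - pX
  if (d <= 0) stop("zero residual degrees of freedom")
  coefs <- qr.coef(qrX, t(mat))                    # pX x features
  resid <- t(mat) - X %*% coefs
  s2 <- colSums(resid^2) / d
  XtXinv <- chol2inv(qr.R(qrX))
  rownames(XtXinv) <- colnames(XtXinv) <- colnames(X)

  if (is.null(d0)) {
    prior <- estimate_moderation_prior(s2, d)
  } else {
    prior <- list(d0 = d0,
                  s0_sq = s0_sq %||%
                    (if (d0 > 0) estimate_moderation_prior(s2, d)$s0_sq else NA))
  }
  s2_tilde <- if (is.infinite(prior$d0)) rep(prior$s0_sq, length(s2))
  else if (prior$d0 == 0) s2
  else (prior$d0 * prior$s0_sq + d * s2) / (prior$d0 + d)
  df_total <- prior$d0 + d

  lvls <- levels(groups)
  if (is.null(pairs))
    pairs <- utils::combn(lvls, 2, simplify = FALSE)
  res <- list()
  for (pr in pairs) {
    a <- pr[1]; b_lvl <- pr[2]
    cvec <- numeric(pX); names(cvec) <- colnames(X)
    if (a != lvls[1]) cvec[paste0("group", a)] <- 1
    if (b_lvl != lvls[1]) cvec[paste0("group", b_lvl)] <- -1
    b <- drop(crossprod(cvec, coefs))
    cunit <- sqrt(drop(t(cvec) %*% XtXinv %*% cvec))
    se <- sqrt(s2_tilde) * cunit
    tstat <- sign(b) * pmax(abs(b) - theta, 0) / se
    p <- 2 * stats::pt(-abs(tstat), df = df_total)
    q <- stats::p.adjust(p, "BH")
    res[[paste0(a, "_vs_", b_lvl)]] <- data.frame(
      feature = rownames(mat), b = b, se = se, t = tstat,
      df = df_total, p = p, q = q,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(res, class = "diff_result", prior = prior, theta = theta,
            residual_df = d)
}

#' @export
print.diff_result <- function(x, q_max = 0.05, ...) {
  prior <- attr(x, "prior")
  cat(sprintf("Moderated pairwise tests (theta = %g, d0 = %.3g, s0^2 = %.3g)\n",
              attr(x, "theta"), prior$d0, prior$s0_sq))
  for (nm in names(x))
    cat(sprintf("  %s: %d / %d features at q < %g\n", nm,
                sum(x[[nm]]$q < q_max), nrow(x[[nm]]), q_max))
  invisible(x)
}

#' Core features of a focal group
#'
#' The intersection, over every pairwise comparison involving the focal group,
#' of features significant at `q_max` — optionally (default) requiring a
#' consistent effect direction relative to the focal group, so a core feature
#' is focal-specifically up or down everywhere.
#'
#' @param results a `diff_result` (pair names `A_vs_B`).
#' @param focal focal group label.
#' @param q_max significance bound (default 0.05).
#' @param require_direction demand consistent sign across pairs.
#' @return character vector of core feature ids.
#' @export
core_features <- function(results, focal, q_max = 0.05,
                          require_direction = TRUE) {
  parts <- strsplit(names(results), "_vs_", fixed = TRUE)
  involve <- vapply(parts, function(p) focal %in% p, logical(1))
  if (!any(involve)) stop("no pairwise result involves group ", focal)
  sets <- list(); signs <- list()
  for (i in which(involve)) {
    df <- results[[i]]
    eff <- if (parts[[i]][1] == focal) df$b else -df$b
    sig <- df$q < q_max
    sets[[length(sets) + 1]] <- df$feature[sig]
    s <- sign(eff); names(s) <- df$feature
    signs[[length(signs) + 1]] <- s
  }
  core <- Reduce(intersect, sets)
  if (require_direction && length(core)) {
    sgn <- vapply(signs, function(s) s[core], numeric(length(core)))
    sgn <- matrix(sgn, nrow = length(core))
    consistent <- apply(sgn, 1, function(r) all(r == r[1]) && r[1] != 0)
    core <- core[consistent]
  }
  core
}

#' Map CpGs to gene promoters by TSS distance
#'
#' A CpG maps to a gene when it lies within `window` bases of the gene's
#' transcription start site on the same chromosome (boundary inclusive); a
#' CpG may map to several genes, and chromosome mismatches simply leave it
#' unmapped.
#'
#' @param cpg_annotation data frame (feature, chrom, pos) for CpGs.
#' @param tss_annotation data frame (feature, chrom, pos) for gene TSSs.
#' @param window half-width in bases (default 2000).
#' @return data frame (cpg, gene, distance).
#' @export
map_cpgs_to_promoters <- function(cpg_annotation, tss_annotation,
                                  window = 2000L) {
  out <- list()
  for (ch in unique(cpg_annotation$chrom)) {
    cp <- cpg_annotation[cpg_annotation$chrom == ch, , drop = FALSE]
    ts <- tss_annotation[tss_annotation$chrom == ch, , drop = FALSE]
    if (nrow(ts) == 0 || nrow(cp) == 0) next
    dmat <- abs(outer(cp$pos, ts$pos, "-"))
    hit <- which(dmat <= window, arr.ind = TRUE)
    if (nrow(hit))
      out[[ch]] <- data.frame(cpg = cp$feature[hit[, 1]],
                              gene = ts$feature[hit[, 2]],
                              distance = dmat[hit],
                              stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(cpg = character(), gene = character(),
                      distance = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$gene, res$cpg), , drop = FALSE]
}

#' Promoter methylation-expression correlation with filters
#'
#' Pearson correlation test per mapped (gene, CpG) pair between the CpG's beta
#' values and the gene's normalised expression, BH-adjusted across all pairs.
#' Pairs are retained when `q < q_max`, `r^2 > r2_min` and the interquartile
#' range of the beta values exceeds `iqr_min`; per gene, only the surviving
#' CpG with the smallest q is reported.
#'
#' @param expression gene x sample normalised expression.
#' @param beta CpG x sample beta values.
#' @param mapping data frame from [map_cpgs_to_promoters()].
#' @param q_max,r2_min,iqr_min the filters (defaults 0.05, 0.5, 0.25).
#' @return data frame (gene, cpg, r, r2, iqr, p, q, direction), one row per
#'   gene with a surviving CpG.
#' @export
expr_meth_correlation <- function(expression, beta, mapping, q_max = 0.05,
                                  r2_min = 0.5, iqr_min = 0.25) {
  mapping <- mapping[mapping$gene %in% rownames(expression) &
                       mapping$cpg %in% rownames(beta), , drop = FALSE]
  shared <- intersect(colnames(expression), colnames(beta))
  rows <- list()
  for (i in seq_len(nrow(mapping))) {
    g <- mapping$gene[i]; c_ <- mapping$cpg[i]
    x <- beta[c_, shared]; y <- expression[g, shared]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) next
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    rows[[i]] <- data.frame(gene = g, cpg = c_, r = unname(ct$estimate),
                            iqr = stats::IQR(x[ok]), p = ct$p.value,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene = character(), cpg = character(), r = numeric(),
                      r2 = numeric(), iqr = numeric(), p = numeric(),
                      q = numeric(), direction = character()))
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, "BH")
  res$r2 <- res$r^2
  keep <- res$q < q_max & res$r2 > r2_min & res$iqr > iqr_min
  res <- res[keep, , drop = FALSE]
  if (nrow(res)) {
    res <- res[order(res$gene, res$q), , drop = FALSE]
    res <- res[!duplicated(res$gene), , drop = FALSE]
  }
  res$direction <- ifelse(res$r < 0, "negative", "positive")
  rownames(res) <- NULL
  res[, c("gene", "cpg", "r", "r2", "iqr", "p", "q", "direction")]
}
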