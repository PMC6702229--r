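#' Prepare omic blocks for joint factorisation
#'
#' Centres each block per feature and rescales it to unit total variance so
#' that neither block dominates the stacked decomposition. Blocks may cover
#' different (overlapping) sample sets; the union defines the model's samples
#' and a block's missing samples become missing columns.
#'
#' @param blocks named list of feature x sample matrices on their analysis
#'   scale (normalised expression, M-values).
#' @return list with `X` (stacked feature x union-sample matrix, NA where a
#'   block lacks a sample), `block_rows` (row index per block), `scales`.
#' @keywords internal
prepare_blocks <- function(blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 1, !is.null(names(blocks)))
  samples <- Reduce(union, lapply(blocks, colnames))
  pieces <- list(); scales <- numeric(0); block_rows <- list(); at <- 0
  for (nm in names(blocks)) {
    b <- as.matrix(blocks[[nm]])
    b <- b - rowMeans(b)                      # centre per feature
    tot <- sum(b^2) / (ncol(b) - 1)           # total variance of the block
    if (tot <= 0) stop("block ", nm, " has zero total variance")
    b <- b / sqrt(tot)
    full <- matrix(NA_real_, nrow(b), length(samples),
                   dimnames = list(paste(nm, rownames(b), sep = ":"), samples))
    full[, colnames(b)] <- b
    pieces[[nm]] <- full
    block_rows[[nm]] <- at + seq_len(nrow(b))
    at <- at + nrow(b)
    scales[nm] <- sqrt(tot)
  }
  X <- do.call(rbind, pieces)
  present <- colSums(!is.na(X)) > 0
  if (!all(present)) stop("samples present in no block: ",
                          paste(samples[!present], collapse = ", "))
  list(X = X, block_rows = block_rows, scales = scales)
}

#' Joint latent-factor decomposition of multiple omic blocks
#'
#' Deterministic surrogate for variational multi-omics factor analysis:
#' blocks are feature-centred, rescaled to unit total variance, stacked, and
#' decomposed by an EM-style truncated SVD that iteratively imputes entries of
#' missing sample blocks from the current rank-K reconstruction (initial
#' imputation: zeros, or seeded noise for stability runs). Sample scores are
#' `Z = V D`, loadings `W = U` split back by block; factors are ordered by
#' total variance explained and signed so each factor's largest-magnitude
#' loading is positive.
#'
#' @param blocks named list of feature x sample matrices (see
#'   [prepare_blocks()]), or a prepared list from that function.
#' @param K number of factors; must be below `min(total features, samples)`.
#' @param tol relative-change convergence tolerance on the reconstruction.
#' @param obj_tol secondary stopping rule: stop once the relative per-iteration
#'   decrease of the observed-data residual sum of squares falls below this
#'   (the objective plateaus long before near-degenerate noise factors stop
#'   rotating, so waiting for `tol` alone can waste hundreds of iterations).
#' @param max_iter iteration cap; non-convergence returns the fit with a
#'   warning and `converged = FALSE`.
#' @param init_noise_sd sd of seeded Gaussian noise used as initial imputation
#'   (0 = zeros; used by [factor_stability()]).
#' @param seed seed for the initial imputation noise.
#' @return an object of class `factor_model` with elements `Z`
#'   (sample x K scores), `W` (list of per-block feature x K loadings),
#'   `varexp` (block x factor fraction-of-variance matrix), `d` (singular
#'   values), `iterations`, `final_change`, `converged`.
#' @export
fit_joint_factors <- function(blocks, K = 5L, tol = 1e-6, obj_tol = 1e-4,
                              max_iter = 300L,
                              init_noise_sd = 0, seed = NULL) {
  prep <- if (is.list(blocks) && !is.null(blocks$X) &&
              !is.null(blocks$block_rows)) blocks else prepare_blocks(blocks)
  X <- prep$X
  n <- ncol(X); p <- nrow(X)
  if (K >= min(p, n)) stop("K must be below min(total features, samples)")
  miss <- is.na(X)
  Ximp <- X
  if (any(miss)) {
    if (init_noise_sd > 0) {
      if (!is.null(seed)) set.seed(seed)
      Ximp[miss] <- stats::rnorm(sum(miss), sd = init_noise_sd)
    } else Ximp[miss] <- 0
  }
  total_ss <- sum(X[!miss]^2)
  prev <- NULL; change <- Inf; it <- 0
  objective <- numeric(0); stalled <- FALSE
  repeat {
    it <- it + 1
    sv <- svd(Ximp, nu = K, nv = K)
    recon <- sv$u %*% (sv$d[seq_len(K)] * t(sv$v))
    obj <- sum((X[!miss] - recon[!miss])^2)
    objective[it] <- obj
    if (!is.null(prev)) {
      change <- sqrt(sum((recon - prev)^2)) / max(sqrt(sum(prev^2)), 1e-300)
      if (change < tol) break
      rel_decr <- (objective[it - 1] - obj) / max(obj, 1e-300)
      if (obj <= 1e-12 * total_ss || rel_decr < obj_tol) {
        stalled <- TRUE
        break
      }
    }
    if (!any(miss) && it >= 1) { change <- 0; break }  # exact in one pass
    if (it >= max_iter) break
    prev <- recon
    Ximp[miss] <- recon[miss]
  }
  converged <- change < tol || stalled || !any(miss)
  if (!converged)
    warning("EM-SVD did not converge in ", max_iter,
            " iterations (relative change ", signif(change, 3), ")")

  W <- sv$u; Z <- sv$v %*% diag(sv$d[seq_len(K)], K)
  rownames(Z) <- colnames(X)
  rownames(W) <- rownames(X)

  # per-block variance explained over observed entries
  varexp <- matrix(0, length(prep$block_rows), K,
                   dimnames = list(names(prep$block_rows), NULL))
  for (m in names(prep$block_rows)) {
    rows <- prep$block_rows[[m]]
    obs_cols <- colSums(!miss[rows, , drop = FALSE]) > 0
    tot <- sum(X[rows, obs_cols]^2)
    for (k in seq_len(K))
      varexp[m, k] <- sum(W[rows, k]^2) * sum(Z[obs_cols, k]^2) / tot
  }

  # order by total variance explained, fix signs
  ord <- order(-colSums(varexp))
  W <- W[, ord, drop = FALSE]; Z <- Z[, ord, drop = FALSE]
  varexp <- varexp[, ord, drop = FALSE]
  d <- sv$d[seq_len(K)][ord]
  for (k in seq_len(K)) {
    if (W[which.max(abs(W[, k])), k] < 0) {
      W[, k] <- -W[, k]; Z[, k] <- -Z[, k]
    }
  }
  colnames(Z) <- colnames(W) <- colnames(varexp) <- paste0("LF", seq_len(K))

  Wsplit <- lapply(prep$block_rows, function(rows) {
    out <- W[rows, , drop = FALSE]
    rownames(out) <- sub("^[^:]+:", "", rownames(out))
    out
  })
  structure(list(Z = Z, W = Wsplit, varexp = varexp, d = d,
                 scales = prep$scales, iterations = it,
                 final_change = change, converged = converged,
                 objective = objective, block_rows = prep$block_rows),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("Joint factor model: %d factors, %d samples, blocks: %s\n",
              ncol(x$Z), nrow(x$Z), paste(names(x$W), collapse = ", ")))
  cat("Variance explained (%):\n")
  print(round(100 * x$varexp, 1))
  if (!x$converged) cat("warning: fit did not converge\n")
  invisible(x)
}

#' @export
summary.factor_model <- function(object, ...) {
  out <- list(varexp = object$varexp,
              total = colSums(object$varexp),
              iterations = object$iterations,
              converged = object$converged)
  class(out) <- "summary.factor_model"
  out
}

#' @export
print.summary.factor_model <- function(x, ...) {
  cat("Variance explained per block (fractions):\n"); print(round(x$varexp, 4))
  cat("Total per factor:\n"); print(round(x$total, 4))
  cat(sprintf("EM-SVD iterations: %d (converged: %s)\n",
              x$iterations, x$converged))
  invisible(x)
}

#' @export
coef.factor_model <- function(object, block = NULL, ...) {
  if (is.null(block)) object$W else object$W[[block]]
}

#' Project new standardized samples onto a fitted factor model
#'
#' Least-squares projection of (already feature-centred/scaled, stacked-order)
#' new data onto the loadings; features missing from `newdata` are dropped
#' from the projection, which is how samples lacking one block obtain scores.
#'
#' @param object a `factor_model`.
#' @param newdata named list of blocks (feature x sample), on the same scale
#'   as the training blocks.
#' @param ... unused.
#' @return sample x K score matrix.
#' @export
predict.factor_model <- function(object, newdata, ...) {
  stacked <- do.call(rbind, lapply(names(newdata), function(nm) {
    b <- as.matrix(newdata[[nm]])
    rownames(b) <- paste(nm, rownames(b), sep = ":")
    b
  }))
  Wall <- do.call(rbind, lapply(names(object$W), function(nm) {
    w <- object$W[[nm]]
    rownames(w) <- paste(nm, rownames(w), sep = ":")
    w
  }))
  common <- intersect(rownames(Wall), rownames(stacked))
  if (length(common) < ncol(object$Z)) stop("too few shared features to project")
  W <- Wall[common, , drop = FALSE]
  X <- stacked[common, , drop = FALSE]
  t(solve(crossprod(W), crossprod(W, X)))
}

#' @export
plot.factor_model <- function(x, factors = c(1, 2), labels = NULL, ...) {
  Z <- x$Z[, factors, drop = FALSE]
  col <- if (is.null(labels)) 1 else as.integer(factor(labels))
  graphics::plot(Z[, 1], Z[, 2], col = col, pch = 19,
                 xlab = colnames(Z)[1], ylab = colnames(Z)[2], ...)
  invisible(x)
}

#' Variance explained by each factor in each block
#'
#' `varexp(m, k) = ||w_mk z_k'||^2 / ||X_m||^2` over the observed entries of
#' block m. Exposed separately so it can be recomputed against the blocks; the
#' fitted model stores the same table.
#'
#' @param model a `factor_model`.
#' @return block x factor matrix of fractions.
#' @export
variance_explained <- function(model) {
  stopifnot(inherits(model, "factor_model"))
  model$varexp
}

#' Retain factors explaining enough variance in at least one block
#'
#' @param model a `factor_model`.
#' @param min_varexp retention threshold (default 0.02: factors explaining
#'   more than 2% of the variance in at least one data set).
#' @return the reduced `factor_model` (order preserved).
#' @export
select_factors <- function(model, min_varexp = 0.02) {
  keep <- apply(model$varexp, 2, max) >= min_varexp
  if (!any(keep)) stop("empty model: no factor reaches min_varexp")
  model$Z <- model$Z[, keep, drop = FALSE]
  model$W <- lapply(model$W, function(w) w[, keep, drop = FALSE])
  model$varexp <- model$varexp[, keep, drop = FALSE]
  model$d <- model$d[keep]
  model
}

#' Stability of factors across perturbed refits
#'
#' Refits the model `n_runs` times with seeded random initial imputations of
#' the missing entries and reports the absolute Pearson correlation of matched
#' factors across run pairs, plus within-run cross-factor correlations. With
#' no missing data the fit is deterministic and all matched correlations are 1.
#'
#' @param blocks named list of blocks as for [fit_joint_factors()].
#' @param K number of factors.
#' @param n_runs number of refits (>= 2).
#' @param seed base seed; run r uses `seed + r`.
#' @param init_noise_sd perturbation scale for the initial imputation.
#' @return list with `matched` (runs x runs x K array of |r| between matched
#'   factors), `cross` (K x K mean absolute within-run cross-factor
#'   correlation), `min_matched`.
#' @export
factor_stability <- function(blocks, K = 5L, n_runs = 20L, seed = 1L,
                             init_noise_sd = 0.1) {
  stopifnot(n_runs >= 2)
  prep <- prepare_blocks(blocks)
  fits <- lapply(seq_len(n_runs), function(r)
    fit_joint_factors(prep, K = K, init_noise_sd = init_noise_sd,
                      seed = seed + r))
  matched <- array(NA_real_, c(n_runs, n_runs, K))
  for (i in seq_len(n_runs)) for (j in seq_len(n_runs)) for (k in seq_len(K))
    matched[i, j, k] <- abs(stats::cor(fits[[i]]$Z[, k], fits[[j]]$Z[, k]))
  cross <- matrix(0, K, K)
  for (i in seq_len(n_runs))
    cross <- cross + abs(stats::cor(fits[[i]]$Z))
  cross <- cross / n_runs
  list(matched = matched, cross = cross,
       min_matched = apply(matched, 3, min))
}

#' Associate latent factors with clinical covariables
#'
#' One linear model per factor with all covariables jointly; when both `sex`
#' and `smoking` (and `age_class` and `smoking`) are among the covariables,
#' the corresponding interactions are included. Per-term p-values are ANOVA F
#' tests (sequential, covariables in the order given); BH adjustment is
#' applied across all (factor, term) pairs.
#'
#' @param model a `factor_model`.
#' @param clinical data frame with `sample_id` and the covariable columns.
#' @param covariables character vector of clinical column names.
#' @param interactions add sex:smoking and age:smoking interactions when those
#'   columns are present.
#' @return data frame (factor, term, p, q, significant at q < 0.05).
#' @export
associate_factors_with_covariates <- function(model, clinical, covariables,
                                              interactions = TRUE) {
  idx <- match(rownames(model$Z), clinical$sample_id)
  if (anyNA(idx)) stop("clinical table lacks samples in the model")
  dat <- clinical[idx, covariables, drop = FALSE]
  for (j in seq_along(dat))
    if (is.character(dat[[j]])) dat[[j]] <- factor(dat[[j]])
  rhs <- covariables
  if (interactions) {
    if (all(c("sex", "smoking") %in% covariables))
      rhs <- c(rhs, "sex:smoking")
    if (all(c("age_class", "smoking") %in% covariables))
      rhs <- c(rhs, "age_class:smoking")
  }
  form <- stats::as.formula(paste("z ~", paste(rhs, collapse = " + ")))
  res <- list()
  for (k in seq_len(ncol(model$Z))) {
    dat$z <- model$Z[, k]
    fit <- try(stats::lm(form, data = dat), silent = TRUE)
    if (inherits(fit, "try-error")) next
    av <- try(stats::anova(fit), silent = TRUE)
    if (inherits(av, "try-error")) {
      warning("singular design for factor ", k, "; terms dropped")
      next
    }
    terms_k <- setdiff(rownames(av), "Residuals")
    res[[k]] <- data.frame(factor = colnames(model$Z)[k], term = terms_k,
                           p = av[terms_k, "Pr(>F)"], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out <- out[!is.na(out$p), , drop = FALSE]
  out$q <- stats::p.adjust(out$p, "BH")
  out$significant <- out$q < 0.05
  rownames(out) <- NULL
  out
}

#' Associate latent factors with recurrent mutations
#'
#' Genes mutated in at least `min_recurrence` samples (and not in all) are
#' tested per factor by a two-sample t-test of factor coordinates between
#' mutated and non-mutated samples; BH across all (gene, factor) tests.
#'
#' @param model a `factor_model`.
#' @param mutations gene x sample 0/1 matrix.
#' @param min_recurrence recurrence threshold (default 3 samples).
#' @return data frame (gene, factor, t, p, q).
#' @export
associate_factors_with_mutations <- function(model, mutations,
                                             min_recurrence = 3L) {
  common <- intersect(rownames(model$Z), colnames(mutations))
  Z <- model$Z[common, , drop = FALSE]
  mut <- mutations[, common, drop = FALSE] > 0
  counts <- rowSums(mut)
  genes <- rownames(mut)[counts >= min_recurrence & counts < length(common)]
  res <- list()
  for (g in genes) for (k in seq_len(ncol(Z))) {
    tt <- stats::t.test(Z[mut[g, ], k], Z[!mut[g, ], k])
    res[[paste(g, k)]] <- data.frame(gene = g, factor = colnames(Z)[k],
                                     t = unname(tt$statistic), p = tt$p.value,
                                     stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(data.frame(gene = character(), factor = character(),
                                      t = numeric(), p = numeric(),
                                      q = numeric()))
  out$q <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}

#' Gene-set enrichment on factor loadings
#'
#' For each factor and feature set, a Wilcoxon rank-sum test compares the
#' loading magnitudes of in-set features against all other features of the
#' same block; BH across all (factor, set) tests. Sets matching fewer than two
#' model features are skipped with a notice.
#'
#' @param model a `factor_model`.
#' @param feature_sets named list of feature-id vectors (see [read_gmt()]).
#' @param block which block's loadings to test (default first).
#' @return data frame (factor, set, statistic, p, q).
#' @export
loading_set_enrichment <- function(model, feature_sets, block = NULL) {
  block <- block %||% names(model$W)[1]
  W <- model$W[[block]]
  res <- list()
  for (s in names(feature_sets)) {
    inset <- rownames(W) %in% feature_sets[[s]]
    if (sum(inset) < 2) {
      message("set ", s, " matches <2 features; skipped")
      next
    }
    for (k in seq_len(ncol(W))) {
      wt <- stats::wilcox.test(abs(W[inset, k]), abs(W[!inset, k]))
      res[[paste(s, k)]] <- data.frame(
        factor = colnames(W)[k], set = s,
        statistic = unname(wt$statistic), p = wt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(data.frame(factor = character(), set = character(),
                                      statistic = numeric(), p = numeric(),
                                      q = numeric()))
  out$q <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}
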