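# Constrained least squares: min ||S f - b||_2 subject to f >= 0 and
# sum(f) <= 1. Solved by non-negative least squares; if the sum constraint is
# violated, the simplex-active case is solved exactly on the NNLS support via
# the KKT system of the equality-constrained problem, with a penalty fallback.
solve_constrained_fractions <- function(S, b) {
  f <- pracma::lsqnonneg(S, b)$x
  if (sum(f) <= 1 + 1e-10) return(pmax(f, 0))
  # sum constraint active: penalty NNLS to locate the support ...
  M <- 1e6 * max(abs(S))
  fp <- pracma::lsqnonneg(rbind(S, M), c(b, M))$x
  support <- which(fp > 1e-9)
  # ... then exact equality-constrained LS on that support
  for (attempt in 1:5) {
    Sp <- S[, support, drop = FALSE]
    k <- length(support)
    kkt <- rbind(cbind(2 * crossprod(Sp), rep(1, k)), c(rep(1, k), 0))
    sol <- try(solve(kkt, c(2 * crossprod(Sp, b), 1)), silent = TRUE)
    if (inherits(sol, "try-error")) break
    fs <- sol[seq_len(k)]
    if (all(fs >= -1e-10)) {
      f <- numeric(ncol(S)); f[support] <- pmax(fs, 0)
      return(f)
    }
    support <- support[fs > 0]
    if (!length(support)) break
  }
  fp / max(1, sum(fp))   # fallback: penalty solution projected to the simplex
}

#' Immune-fraction estimation by sum-constrained non-negative least squares
#'
#' Estimates, per sample, the fraction of each signature cell type in the bulk
#' by solving `min || S f - b ||` subject to `f >= 0` and `sum(f) <= 1`; the
#' remainder `1 - sum(f)` is reported as the "other" (non-immune) fraction.
#' Bulk and signature must share the linear normalised scale.
#'
#' @param bulk per-sample expression on the signature genes: a named vector or
#'   a gene x sample matrix.
#' @param signature gene x cell-type reference matrix, full column rank on the
#'   shared genes.
#' @return an object of class `deconv_result`: `fractions` (sample x cell
#'   type, plus `other`), `residual_norm` per sample.
#' @export
deconvolve <- function(bulk, signature) {
  if (is.null(dim(bulk))) bulk <- matrix(bulk, ncol = 1,
                                         dimnames = list(names(bulk), "sample1"))
  signature <- as.matrix(signature)
  shared <- intersect(rownames(signature), rownames(bulk))
  if (length(shared) < ncol(signature))
    stop("fewer shared genes than cell types")
  S <- signature[shared, , drop = FALSE]
  qrS <- qr(S)
  if (qrS$rank < ncol(S)) {
    bad <- colnames(S)[qrS$pivot[-seq_len(qrS$rank)]]
    stop("signature is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  B <- bulk[shared, , drop = FALSE]
  fr <- t(apply(B, 2, function(b) solve_constrained_fractions(S, b)))
  colnames(fr) <- colnames(S)
  other <- 1 - rowSums(fr)
  resid <- vapply(seq_len(ncol(B)), function(j)
    sqrt(sum((S %*% fr[j, ] - B[, j])^2)), numeric(1))
  fractions <- cbind(fr, other = pmax(other, 0))
  structure(list(fractions = fractions, residual_norm = resid,
                 genes = shared), class = "deconv_result")
}

#' @export
print.deconv_result <- function(x, ...) {
  cat(sprintf("Deconvolution of %d samples on %d signature genes, %d cell types\n",
              nrow(x$fractions), length(x$genes), ncol(x$fractions) - 1))
  cat("Mean fractions:\n")
  print(round(colMeans(x$fractions), 3))
  invisible(x)
}

#' Permutation tests for group differences in cell-type fractions
#'
#' For every cell type and group pair, the statistic is the difference in
#' group means (the linear-model coefficient for a two-level factor). The null
#' is built by permuting group labels: exhaustively when the number of
#' distinct splits is at most `n_perm`, otherwise by seeded Monte Carlo with
#' the add-one correction. BH adjustment across cell types within each pair.
#'
#' @param fractions sample x cell-type matrix (e.g. from [deconvolve()]).
#' @param groups group labels aligned with rows.
#' @param n_perm permutation budget (default 10000).
#' @param seed RNG seed for the Monte-Carlo branch.
#' @return data frame (cell_type, pair, statistic, p, q, exhaustive).
#' @export
group_fraction_tests <- function(fractions, groups, n_perm = 10000L,
                                 seed = 1L) {
  fractions <- as.matrix(fractions)
  groups <- factor(groups)
  lvls <- levels(groups)[table(groups) >= 2]
  if (length(lvls) < 2) stop("need at least two groups with >= 2 samples")
  set.seed(seed)
  res <- list()
  for (pr in utils::combn(lvls, 2, simplify = FALSE)) {
    sel <- groups %in% pr
    g <- droplevels(groups[sel])
    sub <- fractions[sel, , drop = FALSE]
    n1 <- sum(g == pr[1]); ntot <- length(g)
    exhaustive <- choose(ntot, n1) <= n_perm
    splits <- if (exhaustive) utils::combn(ntot, n1, simplify = FALSE)
    pair_rows <- lapply(colnames(sub), function(ct) {
      y <- sub[, ct]
      obs <- mean(y[g == pr[1]]) - mean(y[g == pr[2]])
      if (exhaustive) {
        null <- vapply(splits, function(ii)
          mean(y[ii]) - mean(y[-ii]), numeric(1))
        p <- mean(abs(null) >= abs(obs) - 1e-12)
      } else {
        null <- replicate(n_perm, {
          ii <- sample.int(ntot, n1)
          mean(y[ii]) - mean(y[-ii])
        })
        p <- (sum(abs(null) >= abs(obs) - 1e-12) + 1) / (n_perm + 1)
      }
      data.frame(cell_type = ct, pair = paste(pr, collapse = "_vs_"),
                 statistic = obs, p = p, exhaustive = exhaustive,
                 stringsAsFactors = FALSE)
    })
    pair_df <- do.call(rbind, pair_rows)
    pair_df$q <- stats::p.adjust(pair_df$p, "BH")
    res[[paste(pr, collapse = "_vs_")]] <- pair_df
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
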