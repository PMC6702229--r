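# k-means++ seeding (Arthur & Vassilvitskii): first centre uniform, then each
# subsequent centre drawn with probability proportional to squared distance to
# the nearest chosen centre.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  idx <- sample.int(n, 1)
  centers[1, ] <- X[idx, ]
  if (k == 1) return(centers)
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (j in 2:k) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1, prob = prob)
    centers[j, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X),
                                       byrow = TRUE))^2))
  }
  centers
}

#' K-means on latent factor scores
#'
#' Lloyd k-means with k-means++ initialisation and `n_init` restarts (best
#' within-cluster sum of squares kept). In `"kminus1"` mode the first K-1
#' factors are used (the factors explaining most variation); in `"weighted"`
#' mode all retained factors are used with per-factor weight equal to its
#' total variance-explained fraction applied inside the squared distance
#' (implemented by scaling each coordinate by the square root of its weight,
#' which makes the weighted within-cluster sum of squares the ordinary one on
#' the scaled coordinates).
#'
#' @param model a `factor_model` (already [select_factors()]-reduced).
#' @param K number of clusters.
#' @param mode `"kminus1"` or `"weighted"`.
#' @param seed RNG seed for initialisation.
#' @param n_init random restarts (default 25).
#' @return integer cluster labels named by sample.
#' @export
kmeans_on_factors <- function(model, K, mode = c("kminus1", "weighted"),
                              seed = NULL, n_init = 25L) {
  mode <- match.arg(mode)
  if (K > nrow(model$Z)) stop("K exceeds the number of samples")
  if (!is.null(seed)) set.seed(seed)
  X <- cluster_coordinates(model, K, mode)
  if (K == 1) {
    lab <- rep(1L, nrow(X)); names(lab) <- rownames(model$Z); return(lab)
  }
  best <- NULL
  for (r in seq_len(n_init)) {
    fit <- suppressWarnings(
      stats::kmeans(X, centers = kmeanspp_centers(X, K),
                    iter.max = 100L, algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  lab <- best$cluster
  names(lab) <- rownames(model$Z)
  lab
}

cluster_coordinates <- function(model, K, mode) {
  if (mode == "kminus1") {
    k_use <- max(1L, K - 1L)
    if (ncol(model$Z) < k_use)
      stop("model has fewer than K-1 factors")
    model$Z[, seq_len(k_use), drop = FALSE]
  } else {
    w <- colSums(model$varexp)
    sweep(model$Z, 2, sqrt(w), "*")
  }
}

#' Subsample-replicate consensus clustering on joint factors
#'
#' For each of `R` replicates, a fraction of samples is drawn without
#' replacement, the joint factor model is refitted on the subsample, and
#' k-means ([kmeans_on_factors()]) is run for every K in `K_range`. The
#' consensus value of a sample pair at a given K is the proportion of
#' replicates sampling both in which they co-cluster. Final labels come from
#' agglomerative clustering (median linkage) on distance 1 - C cut into K
#' groups; the Dunn index of each K's partition selects the reported K. By
#' default the Dunn index is evaluated on the consensus dissimilarity 1 - C
#' (a robust K is one whose clusters co-occur in nearly all replicates);
#' `dunn_on = "factors"` evaluates it instead on the full-data factor
#' coordinates of that K's clustering space (Euclidean), which is noticeably
#' more sensitive to single noisy samples.
#'
#' @param blocks named list of feature x sample matrices (analysis scale).
#' @param K_range candidate cluster numbers (default 2:5).
#' @param R replicates (default 100).
#' @param subsample fraction of samples per replicate (default 0.8).
#' @param mode passed to [kmeans_on_factors()].
#' @param seed RNG seed.
#' @param n_factors factors fitted per replicate; all are kept, so the
#'   unweighted K-1 rule is feasible for every K up to `n_factors + 1` and the
#'   weighted mode can downweight trailing noise factors by their variance
#'   share.
#' @param n_init k-means restarts per replicate (fewer than the final
#'   clustering's default keeps R replicates affordable).
#' @return an object of class `consensus_result`: consensus and co-sampling
#'   matrices per K, labels per K, Dunn index per K, `chosen_K`, settings.
#' @export
consensus_cluster <- function(blocks, K_range = 2:5, R = 100L,
                              subsample = 0.8,
                              mode = c("kminus1", "weighted"),
                              seed = 1L, n_factors = 5L,
                              n_init = 10L, dunn_on = c("consensus", "factors"),
                              replicate_tol = 1e-4,
                              replicate_max_iter = 100L) {
  dunn_on <- match.arg(dunn_on)
  mode <- match.arg(mode)
  stopifnot(R >= 2, subsample > 0, subsample <= 1)
  if (max(K_range) > n_factors + 1)
    stop("K_range requires more factors: fit at least max(K_range) - 1")
  set.seed(seed)
  prep <- prepare_blocks(blocks)
  samples <- colnames(prep$X)
  n <- length(samples)
  m <- ceiling(subsample * n)

  full_fit <- suppressWarnings(fit_joint_factors(prep, K = n_factors))

  co_cluster <- co_sample <- lapply(K_range, function(k)
    matrix(0, n, n, dimnames = list(samples, samples)))
  names(co_cluster) <- names(co_sample) <- as.character(K_range)

  for (r in seq_len(R)) {
    idx <- sort(sample.int(n, m))
    sub_blocks <- lapply(blocks, function(b) {
      keep <- intersect(samples[idx], colnames(b))
      b[, keep, drop = FALSE]
    })
    fit <- try(suppressWarnings(
      fit_joint_factors(prepare_blocks(sub_blocks), K = n_factors,
                        tol = replicate_tol,
                        max_iter = replicate_max_iter)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    for (k in K_range) {
      lab <- kmeans_on_factors(fit, k, mode = mode, n_init = n_init)
      ids <- match(names(lab), samples)
      same <- outer(lab, lab, "==") * 1
      co_cluster[[as.character(k)]][ids, ids] <-
        co_cluster[[as.character(k)]][ids, ids] + same
      co_sample[[as.character(k)]][ids, ids] <-
        co_sample[[as.character(k)]][ids, ids] + 1
    }
  }

  consensus <- labels <- list(); dunn <- numeric(length(K_range))
  names(dunn) <- as.character(K_range)
  for (k in K_range) {
    ck <- as.character(k)
    cs <- co_sample[[ck]]
    if (any(cs == 0))
      stop("insufficient replicates: some sample pair was never co-sampled; increase R")
    C <- co_cluster[[ck]] / cs
    diag(C) <- 1
    consensus[[ck]] <- C
    hc <- stats::hclust(stats::as.dist(1 - C), method = "median")
    lab <- stats::cutree(hc, k = k)
    labels[[ck]] <- lab
    dunn[ck] <- if (dunn_on == "consensus") dunn_from_dist(1 - C, lab)
    else {
      coords <- cluster_coordinates(full_fit, k, mode)
      dunn_index(coords[names(lab), , drop = FALSE], lab)
    }
  }
  chosen <- K_range[which.max(dunn)]
  structure(list(consensus = consensus, co_sample = co_sample,
                 labels = labels, dunn = dunn, chosen_K = chosen,
                 K_range = K_range, R = R, subsample = subsample,
                 mode = mode, dunn_on = dunn_on, factor_model = full_fit),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus clustering: R = %d replicates, subsample = %.0f%%, mode = %s\n",
              x$R, 100 * x$subsample, x$mode))
  cat("Dunn index per K:\n"); print(round(x$dunn, 3))
  cat("Chosen K:", x$chosen_K, "\n")
  cat("Cluster sizes at chosen K:",
      paste(table(x$labels[[as.character(x$chosen_K)]]), collapse = ", "), "\n")
  invisible(x)
}

dunn_from_dist <- function(D, labels) {
  labels <- as.character(labels)
  cl <- unique(labels)
  if (length(cl) < 2) stop("need at least two non-empty clusters")
  min_between <- Inf; max_diam <- 0
  for (i in seq_along(cl)) {
    ii <- labels == cl[i]
    if (sum(ii) > 1) max_diam <- max(max_diam, max(D[ii, ii]))
    for (j in seq_along(cl)) if (j > i) {
      jj <- labels == cl[j]
      min_between <- min(min_between, min(D[ii, jj]))
    }
  }
  if (max_diam == 0) return(Inf)
  min_between / max_diam
}

#' Dunn index of a partition
#'
#' Minimum between-cluster distance (over all cluster pairs, minimum pairwise
#' Euclidean distance) divided by the maximum cluster diameter. Duplicated
#' clusters at distance zero give 0; an all-singleton partition with zero
#' maximum diameter gives +Inf.
#'
#' @param points sample x coordinate matrix.
#' @param labels cluster labels aligned with rows of `points`.
#' @return a single number in \[0, Inf\].
#' @export
dunn_index <- function(points, labels) {
  points <- as.matrix(points)
  dunn_from_dist(as.matrix(stats::dist(points)), labels)
}

#' Nestedness of consensus partitions across K
#'
#' Diagnostic only: for consecutive K in the result, the fraction of sample
#' pairs co-clustered at the larger K that are also co-clustered at the
#' smaller K (1 = perfectly nested).
#'
#' @param result a `consensus_result`.
#' @return named numeric vector, one entry per consecutive K pair.
#' @export
cluster_nestedness <- function(result) {
  ks <- result$K_range
  out <- numeric(0)
  for (i in seq_along(ks)[-1]) {
    a <- result$labels[[as.character(ks[i - 1])]]
    b <- result$labels[[as.character(ks[i])]]
    pa <- outer(a, a, "==")[upper.tri(diag(length(a)))]
    pb <- outer(b, b, "==")[upper.tri(diag(length(b)))]
    out[paste0(ks[i], "in", ks[i - 1])] <-
      if (any(pb)) mean(pa[pb]) else NA_real_
  }
  out
}
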