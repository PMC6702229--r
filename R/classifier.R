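#' Leave-one-out random-forest class probabilities for one omic block
#'
#' For each fold, feature filtering, variance-fraction feature selection and
#' centring/scaling are learned on the training samples only
#' ([fit_normalization()]); minority classes are then oversampled with
#' replacement to the majority size; a random forest is trained and the
#' held-out sample's class probabilities are the fractions of trees voting for
#' each class. Samples declared as technical replicates share a fold, so two
#' replicates are never split across training and test.
#'
#' @param block feature x sample matrix on the raw scale (counts or beta).
#' @param labels named (or block-ordered) class labels.
#' @param kind `"expression"` or `"methylation"` (sets the variance fraction:
#'   50% / 5%).
#' @param fraction override the variance fraction.
#' @param ntree forest size (default 500).
#' @param mtry candidate features per split (default `floor(sqrt(p))`).
#' @param seed RNG seed (per-fold seeds derive from it).
#' @param replicates optional grouping vector marking technical replicates;
#'   defaults to one fold per sample.
#' @return sample x class probability matrix (rows sum to 1).
#' @export
loocv_predict <- function(block, labels, kind = c("expression", "methylation"),
                          fraction = NULL, ntree = 500L, mtry = NULL,
                          seed = 1L, replicates = NULL) {
  kind <- match.arg(kind)
  block <- as.matrix(block)
  n <- ncol(block)
  labels <- factor(labels)
  if (length(labels) != n) stop("labels must align with block columns")
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least two classes")
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("classes with a single sample skipped: ",
            paste(small, collapse = ", "))
    keep <- !labels %in% small
    block <- block[, keep, drop = FALSE]
    labels <- droplevels(labels[keep])
    if (!is.null(replicates)) replicates <- replicates[keep]
    n <- ncol(block)
  }
  folds <- if (is.null(replicates)) seq_len(n) else as.integer(factor(replicates))
  classes <- levels(labels)
  prob <- matrix(NA_real_, n, length(classes),
                 dimnames = list(colnames(block), classes))
  for (f in unique(folds)) {
    test <- which(folds == f)
    train <- which(folds != f)
    model <- fit_normalization(block[, train, drop = FALSE], kind = kind,
                               fraction = fraction)
    if (length(model$selected) == 0) stop("empty feature set after filtering")
    xtr <- t(apply_normalization(model, block[, train, drop = FALSE]))
    ytr <- droplevels(labels[train])
    # oversample minority classes with replacement to the majority size
    set.seed(stage_seed(seed, paste0("fold", f)))
    counts <- table(ytr)
    idx <- unlist(lapply(names(counts), function(cl) {
      members <- which(ytr == cl)
      c(members, sample(members, max(counts) - length(members), replace = TRUE))
    }))
    xte <- t(apply_normalization(model, block[, test, drop = FALSE]))
    rf <- randomForest::randomForest(
      x = xtr[idx, , drop = FALSE], y = ytr[idx], ntree = ntree,
      mtry = mtry %||% max(1, floor(sqrt(ncol(xtr)))))
    p <- stats::predict(rf, xte, type = "prob")   # fraction of tree votes
    prob[test, colnames(p)] <- p
  }
  prob[is.na(prob)] <- 0
  prob
}

#' Classify from probabilities with an Unclassified category
#'
#' A sample is "Unclassified" when the ratio of its two highest class
#' probabilities is strictly below `rho` (a ratio exactly equal to `rho`
#' classifies); an exact tie of the two top probabilities is always
#' Unclassified since the argmax is undefined.
#'
#' @param probabilities a probability vector, or a sample x class matrix.
#' @param rho ratio threshold (default 1.5).
#' @return a label, or a vector of labels for matrix input.
#' @export
classify_with_unclassified <- function(probabilities, rho = 1.5) {
  if (is.matrix(probabilities))
    return(apply(probabilities, 1, classify_with_unclassified, rho = rho))
  p <- probabilities
  if (length(p) < 2) stop("need at least two classes")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
    stop("probabilities must be non-negative and sum to 1")
  ord <- order(p, decreasing = TRUE)
  p1 <- p[ord[1]]; p2 <- p[ord[2]]
  if (p1 == p2) return("Unclassified")
  ratio <- if (p2 == 0) Inf else p1 / p2
  if (ratio < rho) "Unclassified" else names(p)[ord[1]] %||% as.character(ord[1])
}

#' Merge expression-based and methylation-based predictions
#'
#' One omic only: that prediction. Equal predictions: that label. One
#' Unclassified plus one class: the class (the histopathology-informed omic
#' wins over indecision). Two different classes: Unclassified.
#'
#' @param pred_expr,pred_meth labels (may be NA for a missing omic).
#' @return merged label vector.
#' @export
merge_predictions <- function(pred_expr, pred_meth) {
  n <- max(length(pred_expr), length(pred_meth))
  pred_expr <- rep_len(as.character(pred_expr), n)
  pred_meth <- rep_len(as.character(pred_meth), n)
  mapply(function(e, m) {
    if (is.na(e) && is.na(m)) stop("both predictions absent")
    if (is.na(e)) return(m)
    if (is.na(m)) return(e)
    if (e == m) return(e)
    if (e == "Unclassified") return(m)
    if (m == "Unclassified") return(e)
    "Unclassified"
  }, pred_expr, pred_meth, USE.NAMES = FALSE)
}

#' Prediction groups for survival comparison
#'
#' Groups samples by (histology, merged prediction) pairs — e.g. atypical
#' predicted as typical — pooling all Unclassified samples into one group, and
#' excludes groups with `min_size` samples or fewer (strictly more than
#' `min_size` required).
#'
#' @param merged merged prediction labels.
#' @param histology histopathology labels.
#' @param min_size exclusion bound (default 10: groups of more than 10
#'   samples are kept).
#' @return data frame (sample index, group, kept flag).
#' @export
prediction_groups <- function(merged, histology, min_size = 10L) {
  stopifnot(length(merged) == length(histology))
  group <- ifelse(merged == "Unclassified", "Unclassified",
                  ifelse(histology == merged, merged,
                         paste0(histology, "_pred_", merged)))
  sizes <- table(group)
  data.frame(group = group, kept = group %in% names(sizes)[sizes > min_size],
             stringsAsFactors = FALSE)
}

#' Dual-omic classification of a cohort
#'
#' Runs [loocv_predict()] on the expression and methylation blocks (each on
#' the samples where that block exists), applies the Unclassified rule per
#' omic and merges the two predictions per sample.
#'
#' @param expression gene x sample counts (or NULL).
#' @param methylation CpG x sample beta values (or NULL).
#' @param labels named class labels covering all samples.
#' @param rho Unclassified ratio threshold.
#' @param ntree,seed forwarded to [loocv_predict()].
#' @return an object of class `prediction_set`: per-omic probabilities and
#'   labels, merged labels, settings.
#' @export
classify_dual_omics <- function(expression, methylation, labels, rho = 1.5,
                                ntree = 500L, seed = 1L) {
  stopifnot(!is.null(names(labels)))
  run <- function(block, kind) {
    if (is.null(block)) return(NULL)
    loocv_predict(block, labels[colnames(block)], kind = kind,
                  ntree = ntree, seed = seed)
  }
  p_expr <- run(expression, "expression")
  p_meth <- run(methylation, "methylation")
  samples <- union(rownames(p_expr), rownames(p_meth))
  lab <- function(p, s) {
    if (is.null(p) || !(s %in% rownames(p))) return(NA_character_)
    classify_with_unclassified(p[s, ], rho = rho)
  }
  pred_expr <- vapply(samples, lab, character(1), p = p_expr)
  pred_meth <- vapply(samples, lab, character(1), p = p_meth)
  merged <- merge_predictions(pred_expr, pred_meth)
  names(merged) <- samples
  structure(list(prob_expression = p_expr, prob_methylation = p_meth,
                 label_expression = pred_expr, label_methylation = pred_meth,
                 merged = merged, rho = rho, ntree = ntree, seed = seed),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("Dual-omic predictions for %d samples (rho = %g, %d trees)\n",
              length(x$merged), x$rho, x$ntree))
  print(table(merged = x$merged))
  invisible(x)
}
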