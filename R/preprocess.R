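#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors for count matrices: the median, over genes
#' with a positive geometric mean across samples, of the ratio of the sample's
#' count to that geometric mean.
#'
#' @param counts non-negative gene x sample count matrix.
#' @param reference optional per-gene reference profile (geometric means) from
#'   a learned [fit_normalization()] model; when supplied, factors are computed
#'   against it instead of the matrix's own geometric means.
#' @return named per-sample positive numeric vector.
#' @export
size_factors <- function(counts, reference = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(reference)) {
    loggeo <- rowMeans(log(counts))        # -Inf where any zero
    reference <- exp(loggeo)
  }
  use <- is.finite(reference) & reference > 0
  if (!any(use))
    stop("normalisation error: no gene is positive in all samples")
  sf <- apply(counts[use, , drop = FALSE], 2, function(col)
    stats::median(col / reference[use]))
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("normalisation error: non-positive size factor")
  sf
}

#' Learn a normalisation model on a training block
#'
#' Captures everything needed to apply training-set normalisation to held-out
#' samples: the size-factor reference profile (expression), the surviving
#' feature list after low-expression filtering (expression) and
#' variance-fraction selection, and per-feature centre/scale statistics.
#' Variances for feature selection are computed on the normalised (expression)
#' or M-value (methylation) scale, unscaled; centring/scaling follows
#' selection.
#'
#' @param block feature x sample matrix: raw counts (`kind = "expression"`) or
#'   beta values (`kind = "methylation"`).
#' @param kind `"expression"` or `"methylation"`.
#' @param fraction fraction of total variance the selected features must
#'   explain (defaults: 0.5 expression, 0.05 methylation).
#' @return an object of class `normalization_model`.
#' @export
fit_normalization <- function(block, kind = c("expression", "methylation"),
                              fraction = NULL) {
  kind <- match.arg(kind)
  if (is.null(fraction)) fraction <- if (kind == "expression") 0.5 else 0.05
  block <- as.matrix(block)
  if (kind == "expression") {
    block <- filter_low_expression(block)
    reference <- exp(rowMeans(log(block)))
    norm <- normalize_expression(block, reference = reference)
  } else {
    reference <- NULL
    norm <- beta_to_m(clamp_beta(block))
  }
  selected <- select_variable_features(norm, fraction)
  sub <- norm[selected, , drop = FALSE]
  centre <- rowMeans(sub)
  scale <- apply(sub, 1, stats::sd)
  scale[scale == 0] <- 1
  structure(list(kind = kind, reference = reference, selected = selected,
                 centre = centre, scale = scale, fraction = fraction),
            class = "normalization_model")
}

#' Apply a learned normalisation model to (held-out) samples
#'
#' Size factors for new samples are computed against the model's reference
#' profile; feature selection, centring and scaling reuse the training
#' statistics, so a training sample passed back through the model reproduces
#' its training-time values exactly.
#'
#' @param model a `normalization_model`.
#' @param block feature x sample matrix on the raw scale (counts or beta).
#' @return selected-feature x sample matrix, centred and scaled.
#' @export
apply_normalization <- function(model, block) {
  stopifnot(inherits(model, "normalization_model"))
  block <- as.matrix(block)
  if (model$kind == "expression") {
    missing <- setdiff(names(model$reference), rownames(block))
    if (length(missing)) stop("block lacks reference genes: ", missing[1])
    block <- block[names(model$reference), , drop = FALSE]
    norm <- normalize_expression(block, reference = model$reference)
  } else {
    norm <- beta_to_m(clamp_beta(block))
  }
  sub <- norm[model$selected, , drop = FALSE]
  (sub - model$centre) / model$scale
}

#' Variance-stabilising expression transform
#'
#' `log2(count / size_factor + 1)`, the package's surrogate for a count-model
#' variance-stabilising transform. With `reference` supplied (a learned
#' per-gene geometric-mean profile), size factors are computed against it,
#' which is how training-set normalisation is applied to held-out samples.
#'
#' @param counts non-negative count matrix (genes x samples).
#' @param size_factors optional precomputed per-sample factors.
#' @param reference optional reference profile passed to [size_factors()].
#' @return matrix of normalised values, same dimensions as `counts`.
#' @export
normalize_expression <- function(counts, size_factors = NULL,
                                 reference = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(size_factors))
    size_factors <- size_factors(counts, reference = reference)
  log2(sweep(counts, 2, size_factors, "/") + 1)
}

#' Remove genes expressed in fewer than two samples
#'
#' Keeps genes with counts-per-million >= 1 in at least 2 samples.
#'
#' @param counts gene x sample count matrix.
#' @param cpm_min,min_samples the filtering rule (defaults 1 CPM, 2 samples).
#' @return the filtered count matrix.
#' @export
filter_low_expression <- function(counts, cpm_min = 1, min_samples = 2L) {
  counts <- as.matrix(counts)
  cpm <- sweep(counts, 2, colSums(counts), "/") * 1e6
  keep <- rowSums(cpm >= cpm_min) >= min_samples
  counts[keep, , drop = FALSE]
}

#' Beta to M-value transform and back
#'
#' `M = log2(beta / (1 - beta))`; the inverse is exact. Values at 0 or 1 are a
#' domain error: callers clamp first (see [clamp_beta()]).
#'
#' @param beta matrix or vector of methylation fractions strictly inside (0,1).
#' @return matrix/vector of M-values.
#' @export
beta_to_m <- function(beta) {
  if (any(beta <= 0 | beta >= 1)) stop("beta values must lie strictly in (0, 1)")
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @param m matrix or vector of M-values.
#' @export
m_to_beta <- function(m) 1 / (1 + 2^(-m))

#' @rdname beta_to_m
#' @param eps clamping bound.
#' @export
clamp_beta <- function(beta, eps = 1e-6) pmin(pmax(beta, eps), 1 - eps)

#' Select the most variable features explaining a variance fraction
#'
#' Features are ranked by decreasing per-feature variance (ties broken by
#' feature id order); the smallest prefix whose cumulative variance reaches
#' `fraction` of the total variance is returned.
#'
#' @param x feature x sample matrix on the scale whose variance matters
#'   (normalised expression or M-values).
#' @param fraction target fraction in (0, 1].
#' @return character vector of selected feature ids.
#' @export
select_variable_features <- function(x, fraction) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  if (ncol(x) < 2) stop("need at least two samples to compute variances")
  v <- apply(x, 1, stats::var)
  ord <- order(-v, rownames(x))
  v <- v[ord]
  total <- sum(v)
  if (total == 0) return(character(0))
  # zero-variance features add nothing to the cumulative sum, so the prefix
  # stops at the last informative feature even for fraction = 1
  keep <- which(cumsum(v) >= fraction * total - 1e-12)[1]
  rownames(x)[ord][seq_len(keep)]
}

#' Drop features on the sex chromosomes
#'
#' @param x feature x sample matrix.
#' @param annotation data frame with columns `feature` and `chrom`
#'   (X/Y chromosomes labelled `"chrX"`/`"chrY"` or `"X"`/`"Y"`).
#' @return the matrix without X/Y features.
#' @export
drop_sex_chromosome_features <- function(x, annotation) {
  chrom <- annotation$chrom[match(rownames(x), annotation$feature)]
  if (anyNA(chrom))
    stop("annotation error: no annotation for feature ",
         rownames(x)[which(is.na(chrom))[1]])
  x[!chrom %in% c("chrX", "chrY", "X", "Y"), , drop = FALSE]
}

#' Sex-concordance quality check on expression
#'
#' Sums normalised expression over Y-chromosome (and X-chromosome) genes per
#' sample, splits the Y sums into two groups at the largest gap, and flags
#' samples whose inferred side disagrees with the reported sex.
#'
#' @param counts gene x sample count matrix.
#' @param clinical data frame with `sample_id` and `sex` ("M"/"F"; NA allowed).
#' @param annotation feature annotation as in [drop_sex_chromosome_features()].
#' @return data frame (sample_id, y_sum, x_sum, reported, inferred, flag) with
#'   attribute `status` = "ok" or "skipped" (no Y genes).
#' @export
sex_concordance_check <- function(counts, clinical, annotation) {
  chrom <- annotation$chrom[match(rownames(counts), annotation$feature)]
  y_genes <- rownames(counts)[chrom %in% c("chrY", "Y")]
  x_genes <- rownames(counts)[chrom %in% c("chrX", "X")]
  norm <- normalize_expression(counts)
  res <- data.frame(sample_id = colnames(counts),
                    y_sum = NA_real_, x_sum = NA_real_,
                    reported = clinical$sex[match(colnames(counts),
                                                  clinical$sample_id)],
                    inferred = NA_character_, flag = FALSE,
                    stringsAsFactors = FALSE)
  if (length(y_genes) == 0) {
    warning("no Y-chromosome features: sex-concordance check skipped")
    attr(res, "status") <- "skipped"
    return(res)
  }
  res$y_sum <- colSums(norm[y_genes, , drop = FALSE])
  res$x_sum <- if (length(x_genes))
    colSums(norm[x_genes, , drop = FALSE]) else NA_real_
  # 2-group split of the Y sums at the largest gap
  s <- sort(res$y_sum)
  cut <- if (length(s) > 1) {
    gaps <- diff(s)
    (s[which.max(gaps)] + s[which.max(gaps) + 1]) / 2
  } else s[1]
  res$inferred <- ifelse(res$y_sum > cut, "M", "F")
  res$flag <- !is.na(res$reported) & res$inferred != res$reported
  res$reported[is.na(res$reported)] <- "unknown"
  attr(res, "status") <- "ok"
  res
}
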