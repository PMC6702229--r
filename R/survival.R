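#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper over [survival::survfit()] returning the step function as a
#' data frame. Censored-only data yield S = 1 throughout.
#'
#' @param times non-negative follow-up times (months).
#' @param events 0/1 event indicators.
#' @return data frame (time, n_risk, n_event, surv).
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("empty input")
  stopifnot(all(times >= 0), all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Cox proportional-hazards fit with Wald and logrank tests
#'
#' Newton-Raphson maximisation of the partial likelihood (Efron tie
#' correction by default) via [survival::coxph()]; reports per-level hazard
#' ratios against the reference with Wald 95% CIs and p-values, and the
#' global score (logrank) test.
#'
#' @param times,events follow-up and 0/1 event indicator.
#' @param group factor of group memberships.
#' @param reference reference level (default: first level).
#' @param covariables optional data frame of additional covariates.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return an object of class `nen_coxfit`: data frame `estimates` (level, HR,
#'   CI, Wald z/p, n), `logrank_p`, `reference`, `flagged` (non-convergence or
#'   monotone-likelihood diagnostics), and the underlying `coxph` fit.
#' @export
cox_fit <- function(times, events, group, reference = NULL,
                    covariables = NULL, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (sum(events) < 1) stop("need at least one event")
  group <- factor(group)
  if (!is.null(reference)) {
    if (!reference %in% levels(group)) stop("reference level absent")
    group <- stats::relevel(group, ref = reference)
  }
  dat <- data.frame(times = times, events = events, group = group)
  rhs <- "group"
  if (!is.null(covariables)) {
    dat <- cbind(dat, covariables)
    rhs <- paste(c("group", colnames(covariables)), collapse = " + ")
  }
  form <- stats::as.formula(paste("survival::Surv(times, events) ~", rhs))
  flagged <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(form, data = dat, ties = ties),
    warning = function(w) {
      flagged <<- c(flagged, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  rows <- grep("^group", rownames(sm$coefficients))
  est <- data.frame(
    level = sub("^group", "", rownames(sm$coefficients)[rows]),
    hr = sm$coefficients[rows, "exp(coef)"],
    lower = sm$conf.int[rows, "lower .95"],
    upper = sm$conf.int[rows, "upper .95"],
    z = sm$coefficients[rows, "z"],
    wald_p = sm$coefficients[rows, "Pr(>|z|)"],
    stringsAsFactors = FALSE)
  est$n <- as.integer(table(group)[est$level])
  if (any(!is.finite(fit$coefficients)) ||
      any(abs(fit$coefficients) > 15))
    flagged <- c(flagged, "possible monotone likelihood / separation")
  structure(list(estimates = est,
                 logrank_p = unname(sm$sctest["pvalue"]),
                 reference = levels(group)[1],
                 n = table(group), flagged = flagged, fit = fit),
            class = "nen_coxfit")
}

#' @export
print.nen_coxfit <- function(x, ...) {
  cat("Cox proportional-hazards fit (reference:", x$reference, ")\n")
  est <- x$estimates
  est$hr <- signif(est$hr, 3); est$lower <- signif(est$lower, 3)
  est$upper <- signif(est$upper, 3); est$wald_p <- signif(est$wald_p, 3)
  print(est[, c("level", "hr", "lower", "upper", "wald_p", "n")],
        row.names = FALSE)
  cat("Global logrank (score) p:", signif(x$logrank_p, 3), "\n")
  if (length(x$flagged)) cat("flags:", paste(x$flagged, collapse = "; "), "\n")
  invisible(x)
}

#' Elastic-net Cox gene selection with the one-standard-error rule
#'
#' Coordinate-descent elastic-net Cox over a log-spaced lambda path
#' ([glmnet::cv.glmnet], 100 values spanning four decades), with leave-one-out
#' cross-validated partial-likelihood deviance; the chosen lambda is the most
#' regularised model whose CV deviance is within one standard error of the
#' minimum. Genes with nonzero coefficients at that lambda are returned; an
#' empty selection is a valid (flagged) result.
#'
#' @param times,events follow-up and event indicator.
#' @param X sample x gene matrix, column-standardised by the caller (centred
#'   and scaled normalised counts).
#' @param alpha elastic-net mixing parameter (default 0.5).
#' @param nlambda,lambda_min_ratio path geometry.
#' @return list with `genes`, `coefficients`, `lambda`, `lambda_path`,
#'   `nonzero_path`, `empty` flag and the `cv.glmnet` object.
#' @export
coxnet_select <- function(times, events, X, alpha = 0.5, nlambda = 100L,
                          lambda_min_ratio = 1e-4) {
  stopifnot(sum(events) >= 1)
  X <- as.matrix(X)
  y <- survival::Surv(times, events)
  cv <- glmnet::cv.glmnet(X, y, family = "cox", alpha = alpha,
                          nlambda = nlambda,
                          lambda.min.ratio = lambda_min_ratio,
                          foldid = seq_len(nrow(X)), grouped = TRUE,
                          standardize = FALSE)
  beta <- as.matrix(stats::coef(cv, s = "lambda.1se"))
  sel <- which(beta[, 1] != 0)
  nonzero_path <- cv$glmnet.fit$df
  list(genes = rownames(beta)[sel], coefficients = beta[sel, 1],
       lambda = cv$lambda.1se, lambda_path = cv$lambda,
       nonzero_path = nonzero_path, empty = length(sel) == 0, cv = cv)
}

# standardized logrank (score) statistic of a two-group split, signed by
# (observed - expected) events in the low group
logrank_z <- function(times, events, low) {
  sd <- survival::survdiff(survival::Surv(times, events) ~ low)
  sign(sd$obs[2] - sd$exp[2]) * sqrt(sd$chisq)
}

#' Maximally selected rank-statistic cutpoint
#'
#' Enumerates every cutpoint between consecutive distinct values of `x` that
#' leaves at least `minprop` of the samples on each side, computes the
#' standardized logrank statistic of the induced two-group split, and returns
#' the cutpoint maximising its absolute value together with the (unadjusted)
#' logrank p of the chosen split.
#'
#' @param times,events follow-up and event indicator.
#' @param x per-sample continuous marker (e.g. normalised gene expression).
#' @param minprop minimal proportion of samples per side (default 0.1).
#' @return an object of class `cutpoint_result`: cutpoint, statistic, group
#'   sizes, logrank p, and the enumeration table.
#' @export
maxstat_cutpoint <- function(times, events, x, minprop = 0.1) {
  n <- length(x)
  stopifnot(length(times) == n, length(events) == n)
  xs <- sort(unique(x))
  if (length(xs) < 2) stop("x must have at least two distinct values")
  cand <- (xs[-length(xs)] + xs[-1]) / 2
  nmin <- ceiling(minprop * n)
  valid <- vapply(cand, function(cut) {
    nl <- sum(x <= cut); nl >= nmin && (n - nl) >= nmin
  }, logical(1))
  cand <- cand[valid]
  if (!length(cand)) stop("no valid cutpoint under minprop")
  z <- vapply(cand, function(cut)
    logrank_z(times, events, factor(x > cut, levels = c(FALSE, TRUE))),
    numeric(1))
  best <- which.max(abs(z))
  cut <- cand[best]
  chisq <- z[best]^2
  structure(list(cutpoint = cut, statistic = z[best],
                 n_low = sum(x <= cut), n_high = sum(x > cut),
                 logrank_p = stats::pchisq(chisq, 1, lower.tail = FALSE),
                 candidates = data.frame(cutpoint = cand, z = z)),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("Maximally selected rank statistic: cutpoint %.4g (|z| = %.3f)\n",
              x$cutpoint, abs(x$statistic)))
  cat(sprintf("  groups: %d low / %d high; logrank p = %.3g\n",
              x$n_low, x$n_high, x$logrank_p))
  invisible(x)
}
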