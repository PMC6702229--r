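#' Fisher-exact enrichment of somatic mutations in gene sets
#'
#' For each gene set, a 2x2 contingency table is built over a declared gene
#' universe and tested two-sided with Fisher's exact test. In the default
#' `"events"` mode, mutation events are counted with multiplicity (a gene
#' mutated in two samples of the group contributes two events): the table rows
#' are in-set / out-of-set, the columns mutation events in the group versus
#' universe gene membership. In `"presence"` mode each mutated gene counts
#' once. BH adjustment is applied across sets within the group, with
#' significance flags at q < 0.05 and q < 0.10.
#'
#' @param mutations gene x sample count (or 0/1) matrix for the group's
#'   samples.
#' @param gene_sets named list of gene-id vectors (see [read_gmt()]).
#' @param universe gene universe; default: all genes mutated anywhere in
#'   `mutations` union all set genes. Set genes outside the universe are
#'   reported and ignored.
#' @param mode `"events"` (multiplicity) or `"presence"`.
#' @return an object of class `enrichment_table`: data frame (set, events_in,
#'   events_out, universe_in, universe_out, odds_ratio, p, q, sig_05, sig_10,
#'   genes — contributing mutated genes with multiplicities).
#' @export
hallmark_enrichment <- function(mutations, gene_sets, universe = NULL,
                                mode = c("events", "presence")) {
  mode <- match.arg(mode)
  mutations <- as.matrix(mutations)
  events_per_gene <- rowSums(mutations)
  mutated <- events_per_gene[events_per_gene > 0]
  if (is.null(universe))
    universe <- union(names(mutated), unlist(gene_sets))
  universe <- unique(universe)
  outside <- setdiff(unlist(gene_sets), universe)
  if (length(outside))
    warning("set genes outside the universe ignored: ",
            paste(utils::head(outside, 5), collapse = ", "))
  total_events <- if (mode == "events") sum(mutated)
  else length(mutated)
  rows <- lapply(names(gene_sets), function(s) {
    set <- intersect(gene_sets[[s]], universe)
    in_names <- intersect(names(mutated), set)
    a <- if (mode == "events") sum(mutated[in_names]) else length(in_names)
    b <- total_events - a
    c_ <- length(set)
    d <- length(universe) - c_
    if (total_events == 0) {
      p <- 1; or <- NA_real_
    } else {
      ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
      p <- ft$p.value; or <- unname(ft$estimate)
    }
    genes <- if (length(in_names))
      paste(sprintf("%s(%d)", in_names, mutated[in_names]), collapse = ",")
    else ""
    data.frame(set = s, events_in = a, events_out = b,
               universe_in = c_, universe_out = d,
               odds_ratio = or, p = p, genes = genes,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, "BH")
  out$sig_05 <- out$q < 0.05
  out$sig_10 <- out$q < 0.10
  rownames(out) <- NULL
  structure(out[, c("set", "events_in", "events_out", "universe_in",
                    "universe_out", "odds_ratio", "p", "q", "sig_05",
                    "sig_10", "genes")],
            class = c("enrichment_table", "data.frame"),
            mode = mode, universe = universe)
}

#' Jackknife leverage of samples or genes on enrichment calls
#'
#' Re-runs [hallmark_enrichment()] leaving out one sample (column) or one
#' mutated gene (row) at a time and reports, per (left-out unit, set), the new
#' q-value and whether the significance flags at 0.05 / 0.10 flip relative to
#' the full analysis.
#'
#' @param mutations gene x sample mutation matrix for the group.
#' @param gene_sets,universe,mode as in [hallmark_enrichment()].
#' @param by `"sample"` or `"gene"`.
#' @return data frame (unit, set, q_full, q_jack, flip_05, flip_10).
#' @export
jackknife_leverage <- function(mutations, gene_sets, universe = NULL,
                               mode = c("events", "presence"),
                               by = c("sample", "gene")) {
  by <- match.arg(by); mode <- match.arg(mode)
  mutations <- as.matrix(mutations)
  full <- hallmark_enrichment(mutations, gene_sets, universe, mode)
  universe <- attr(full, "universe")  # freeze the universe across re-runs
  units <- if (by == "sample") colnames(mutations)
  else rownames(mutations)[rowSums(mutations) > 0]
  if (length(units) < 2) stop("need at least two units to jackknife")
  res <- lapply(units, function(u) {
    sub <- if (by == "sample") mutations[, colnames(mutations) != u,
                                         drop = FALSE]
    else mutations[rownames(mutations) != u, , drop = FALSE]
    jt <- hallmark_enrichment(sub, gene_sets, universe, mode)
    data.frame(unit = u, set = jt$set, q_full = full$q, q_jack = jt$q,
               flip_05 = (jt$q < 0.05) != (full$q < 0.05),
               flip_10 = (jt$q < 0.10) != (full$q < 0.10),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
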