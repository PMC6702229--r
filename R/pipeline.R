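#' Pipeline configuration
#'
#' Collects every stage parameter and toggle. A single global seed drives all
#' stages: each stage derives its own seed deterministically from
#' (global seed, stage name), so stages can be rerun independently yet
#' reproducibly.
#'
#' @param out_dir output directory.
#' @param seed global integer seed.
#' @param cohort_dir optional directory of an existing cohort
#'   ([write_cohort()] layout); when NULL a synthetic cohort is generated.
#' @param sim list of [sim_config()] overrides for the synthetic cohort.
#' @param stages character vector of enabled stages, a subset of the default
#'   order (dependencies are the caller's responsibility; disabling `cluster`
#'   makes downstream group analyses fall back to histology labels).
#' @param n_factors,min_varexp factor model settings.
#' @param K_range,R,subsample,cluster_mode consensus clustering settings.
#' @param rho,ntree classifier settings.
#' @param theta_expression,theta_methylation differential thresholds.
#' @param window promoter window (bp).
#' @param n_perm permutation budget for fraction tests.
#' @param alpha,minprop survival settings.
#' @param gmt path to a GMT file for mutation enrichment (default: the bundled
#'   synthetic hallmark sets).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, cohort_dir = NULL,
                            sim = list(),
                            stages = c("simulate", "preprocess", "factorize",
                                       "cluster", "classify", "diff",
                                       "deconv", "survive", "enrich"),
                            n_factors = 5L, min_varexp = 0.02,
                            K_range = 2:5, R = 100L, subsample = 0.8,
                            cluster_mode = "kminus1",
                            rho = 1.5, ntree = 500L,
                            theta_expression = 2, theta_methylation = 0,
                            window = 2000L, n_perm = 2000L,
                            alpha = 0.5, minprop = 0.1, gmt = NULL) {
  cfg <- as.list(environment())
  cfg$gmt <- gmt %||% system.file("extdata", "hallmarks_synthetic.gmt",
                                  package = "nenstrat")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from a YAML key-value file
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

write_stage <- function(out_dir, name, obj) {
  path <- file.path(out_dir, name)
  if (is.matrix(obj)) write_matrix_tsv(obj, path) else write_df_tsv(obj, path)
  path
}

#' Run the full stratification pipeline
#'
#' Executes the enabled stages in dependency order — simulate/ingest,
#' preprocess, factorize, cluster, classify, diff, deconv, survive, enrich —
#' writing every artifact as TSV plus a manifest recording parameters and
#' derived stage seeds, and finally the summary report. Identical config and
#' seed give byte-identical artifacts. A stage failure halts the pipeline with
#' the failing stage named; artifacts written so far are retained.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list of in-memory stage results and artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  res <- list(artifacts = character(0))
  stage <- function(name, enabled, fun) {
    if (!enabled) return(invisible(NULL))
    tryCatch(fun(), error = function(e)
      stop("pipeline halted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  on <- function(s) s %in% config$stages

  # --- simulate / ingest ----------------------------------------------------
  stage("simulate", TRUE, function() {
    cohort <- if (!is.null(config$cohort_dir)) read_cohort(config$cohort_dir)
    else {
      sim_args <- config$sim
      sim_args$seed <- stage_seed(config$seed, "simulate")
      generate_cohort(do.call(sim_config, sim_args))
    }
    res$cohort <<- cohort
  })
  cohort <- res$cohort
  labels_hist <- cohort$clinical$histology
  names(labels_hist) <- cohort$clinical$sample_id

  # --- preprocess -----------------------------------------------------------
  stage("preprocess", on("preprocess"), function() {
    counts <- filter_low_expression(cohort$expression)
    counts <- drop_sex_chromosome_features(counts, cohort$annotation)
    expr_norm <- normalize_expression(counts)
    mval <- beta_to_m(clamp_beta(cohort$methylation))
    sexcheck <- sex_concordance_check(cohort$expression, cohort$clinical,
                                      cohort$annotation)
    blocks <- list(
      expression = expr_norm[select_variable_features(expr_norm, 0.5), ,
                             drop = FALSE],
      methylation = mval[select_variable_features(mval, 0.05), ,
                         drop = FALSE])
    res$counts <<- counts; res$expr_norm <<- expr_norm; res$mval <<- mval
    res$blocks <<- blocks
    res$artifacts <<- c(res$artifacts,
                        write_stage(out, "sex_concordance.tsv", sexcheck))
  })

  # --- factorize ------------------------------------------------------------
  stage("factorize", on("factorize"), function() {
    fm <- select_factors(fit_joint_factors(res$blocks, K = config$n_factors),
                         config$min_varexp)
    assoc <- associate_factors_with_covariates(
      fm, cohort$clinical,
      intersect(c("histology", "sex", "age_class", "smoking", "stage",
                  "batch"), colnames(cohort$clinical)))
    mut_assoc <- associate_factors_with_mutations(fm, cohort$mutations)
    res$factor_model <<- fm
    res$artifacts <<- c(res$artifacts,
      write_stage(out, "factor_scores.tsv", fm$Z),
      write_stage(out, "variance_explained.tsv", fm$varexp),
      write_stage(out, "factor_covariate_assoc.tsv", assoc),
      write_stage(out, "factor_mutation_assoc.tsv", mut_assoc))
  })

  # --- cluster --------------------------------------------------------------
  groups <- labels_hist   # fallback when clustering is disabled
  stage("cluster", on("cluster"), function() {
    cc <- consensus_cluster(res$blocks, K_range = config$K_range,
                            R = config$R, subsample = config$subsample,
                            mode = config$cluster_mode,
                            seed = stage_seed(config$seed, "cluster"),
                            n_factors = config$n_factors)
    lab <- cc$labels[[as.character(cc$chosen_K)]]
    res$consensus <<- cc
    res$cluster_labels <<- paste0("MC", lab)
    names(res$cluster_labels) <<- names(lab)
    res$artifacts <<- c(res$artifacts,
      write_stage(out, "cluster_labels.tsv",
                  data.frame(sample_id = names(lab),
                             cluster = res$cluster_labels)),
      write_stage(out, "dunn_index.tsv",
                  data.frame(K = cc$K_range, dunn = unname(cc$dunn))),
      write_stage(out, "consensus_matrix.tsv",
                  cc$consensus[[as.character(cc$chosen_K)]]))
  })
  if (!is.null(res$cluster_labels)) groups <- res$cluster_labels

  # --- classify -------------------------------------------------------------
  stage("classify", on("classify"), function() {
    ps <- classify_dual_omics(cohort$expression, cohort$methylation,
                              labels_hist, rho = config$rho,
                              ntree = config$ntree,
                              seed = stage_seed(config$seed, "classify"))
    grp <- prediction_groups(ps$merged,
                             labels_hist[names(ps$merged)])
    res$predictions <<- ps; res$pred_groups <<- grp
    res$artifacts <<- c(res$artifacts,
      write_stage(out, "predictions.tsv",
                  data.frame(sample_id = names(ps$merged),
                             expression = unname(ps$label_expression),
                             methylation = unname(ps$label_methylation),
                             merged = unname(ps$merged),
                             group = grp$group, kept = grp$kept)))
  })

  # --- differential ---------------------------------------------------------
  stage("diff", on("diff"), function() {
    g_expr <- groups[colnames(res$expr_norm)]
    covars <- cohort$clinical[match(colnames(res$expr_norm),
                                    cohort$clinical$sample_id),
                              c("sex", "age_class"), drop = FALSE]
    de <- fit_moderated_pairwise(res$expr_norm, g_expr, covars,
                                 theta = config$theta_expression)
    g_meth <- groups[colnames(res$mval)]
    covars_m <- cohort$clinical[match(colnames(res$mval),
                                      cohort$clinical$sample_id),
                                c("sex", "age_class"), drop = FALSE]
    dm <- fit_moderated_pairwise(res$mval, g_meth, covars_m,
                                 theta = config$theta_methylation)
    lvls <- unique(g_expr)
    cores <- lapply(stats::setNames(lvls, lvls), function(f)
      core_features(de, f))
    ann <- cohort$annotation
    mapping <- map_cpgs_to_promoters(ann[ann$type == "cpg", ],
                                     ann[ann$type == "gene", ],
                                     window = config$window)
    corr <- expr_meth_correlation(res$expr_norm, cohort$methylation, mapping)
    res$de <<- de; res$dm <<- dm; res$cores <<- cores; res$corr <<- corr
    core_df <- data.frame(
      group = rep(names(cores), lengths(cores)),
      feature = unlist(cores, use.names = FALSE))
    res$artifacts <<- c(res$artifacts,
      write_stage(out, "core_genes.tsv", core_df),
      write_stage(out, "expr_meth_correlation.tsv", corr))
    for (nm in names(de))
      res$artifacts <<- c(res$artifacts,
        write_stage(out, paste0("de_", nm, ".tsv"), de[[nm]]))
  })

  # --- deconvolution --------------------------------------------------------
  stage("deconv", on("deconv"), function() {
    sf <- size_factors(cohort$expression)
    bulk <- sweep(cohort$expression, 2, sf, "/")
    dec <- deconvolve(bulk[rownames(cohort$signature), , drop = FALSE] / 60,
                      cohort$signature)
    g <- groups[rownames(dec$fractions)]
    tests <- group_fraction_tests(
      dec$fractions[, colnames(dec$fractions) != "other", drop = FALSE],
      g, n_perm = config$n_perm,
      seed = stage_seed(config$seed, "deconv"))
    res$deconv <<- dec; res$fraction_tests <<- tests
    res$artifacts <<- c(res$artifacts,
      write_stage(out, "immune_fractions.tsv", dec$fractions),
      write_stage(out, "fraction_tests.tsv", tests))
  })

  # --- survival -------------------------------------------------------------
  stage("survive", on("survive"), function() {
    cl <- cohort$clinical
    fits <- list()
    if (!is.null(res$pred_groups) && sum(res$pred_groups$kept) >= 2) {
      keep <- res$pred_groups$kept
      ids <- names(res$predictions$merged)[keep]
      idx <- match(ids, cl$sample_id)
      grp_surv <- res$pred_groups$group[keep]
      fits$prediction_groups <- cox_fit(cl$os_months[idx], cl$os_event[idx],
                                        grp_surv)
    }
    idx <- match(names(groups), cl$sample_id)
    fits$groups <- cox_fit(cl$os_months[idx], cl$os_event[idx], groups)
    km <- km_estimate(cl$os_months, cl$os_event)
    # elastic-net Cox on the core genes of the worst-prognosis group
    coxnet <- NULL; cutpoints <- NULL
    worst <- with(fits$groups, {
      est <- fits$groups$estimates
      if (nrow(est)) est$level[which.max(est$hr)] else NULL
    })
    core <- if (!is.null(res$cores) && !is.null(worst)) res$cores[[worst]]
    if (!is.null(core) && length(core) >= 2) {
      ids <- colnames(res$expr_norm)
      idx <- match(ids, cl$sample_id)
      Xc <- t(res$expr_norm[core, , drop = FALSE])
      Xc <- scale(Xc)
      Xc <- Xc[, apply(Xc, 2, function(v) all(is.finite(v))), drop = FALSE]
      if (ncol(Xc) >= 2 && sum(cl$os_event[idx]) >= 3) {
        coxnet <- try(coxnet_select(cl$os_months[idx], cl$os_event[idx], Xc,
                                    alpha = config$alpha), silent = TRUE)
        if (!inherits(coxnet, "try-error") && length(coxnet$genes)) {
          cutpoints <- lapply(stats::setNames(coxnet$genes, coxnet$genes),
            function(g) maxstat_cutpoint(cl$os_months[idx], cl$os_event[idx],
                                         res$expr_norm[g, ids],
                                         minprop = config$minprop))
        }
      }
    }
    res$survival <<- list(fits = fits, km = km, coxnet = coxnet,
                          cutpoints = cutpoints)
    surv_df <- do.call(rbind, lapply(names(fits), function(nm)
      cbind(analysis = nm, fits[[nm]]$estimates,
            logrank_p = fits[[nm]]$logrank_p)))
    res$artifacts <<- c(res$artifacts,
      write_stage(out, "survival_fits.tsv", surv_df),
      write_stage(out, "km_curve.tsv", km))
    if (!is.null(cutpoints)) {
      cut_df <- data.frame(gene = names(cutpoints),
                           cutpoint = vapply(cutpoints, `[[`, 0, "cutpoint"),
                           logrank_p = vapply(cutpoints, `[[`, 0, "logrank_p"))
      res$artifacts <<- c(res$artifacts,
                          write_stage(out, "maxstat_cutpoints.tsv", cut_df))
    }
  })

  # --- enrichment -----------------------------------------------------------
  stage("enrich", on("enrich"), function() {
    sets <- read_gmt(config$gmt)
    universe <- union(rownames(cohort$mutations)[
      rowSums(cohort$mutations) > 0], unlist(sets))
    per_group <- lapply(split(names(groups), groups), function(ids) {
      ids <- intersect(ids, colnames(cohort$mutations))
      hallmark_enrichment(cohort$mutations[, ids, drop = FALSE], sets,
                          universe = universe)
    })
    enr <- do.call(rbind, lapply(names(per_group), function(g)
      cbind(group = g, as.data.frame(per_group[[g]]))))
    res$enrichment <<- per_group
    res$artifacts <<- c(res$artifacts,
                        write_stage(out, "mutation_enrichment.tsv", enr))
  })

  # --- manifest + report ----------------------------------------------------
  manifest <- unclass(config)
  manifest$K_range <- as.integer(config$K_range)
  manifest$stage_seeds <- stats::setNames(
    lapply(config$stages, function(s) stage_seed(config$seed, s)),
    config$stages)
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  report <- write_report(res, file.path(out, "report.txt"),
                         labels_hist = labels_hist)
  res$artifacts <- c(res$artifacts, file.path(out, "manifest.yaml"), report)
  invisible(res)
}

#' Write the human-readable pipeline summary
#'
#' Summarises the stored stage results: chosen K and the Dunn table, the
#' confusion matrix of merged predictions against histology, prognostic-group
#' sizes, core-feature counts per group, and enrichment significance flags.
#' Empty optional sections are omitted; regeneration from the same results is
#' idempotent.
#'
#' @param results the list returned by [run_pipeline()].
#' @param path output file.
#' @param labels_hist named histology labels (defaults to the cohort's).
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, labels_hist = NULL) {
  if (is.null(labels_hist) && !is.null(results$cohort)) {
    labels_hist <- results$cohort$clinical$histology
    names(labels_hist) <- results$cohort$clinical$sample_id
  }
  lines <- c("Multi-omics stratification report",
             strrep("=", 33), "")
  if (!is.null(results$consensus)) {
    cc <- results$consensus
    lines <- c(lines, sprintf("Consensus clustering: chosen K = %d", cc$chosen_K),
               "Dunn index per K:",
               sprintf("  K=%s: %.4f", names(cc$dunn), cc$dunn), "")
  }
  if (!is.null(results$predictions)) {
    cm <- table(histology = labels_hist[names(results$predictions$merged)],
                predicted = results$predictions$merged)
    lines <- c(lines, "Prediction confusion matrix (histology x merged):",
               utils::capture.output(print(cm)), "")
    if (!is.null(results$pred_groups)) {
      kept <- table(results$pred_groups$group[results$pred_groups$kept])
      if (length(kept))
        lines <- c(lines, "Prognostic prediction groups (kept, >10 samples):",
                   sprintf("  %s: %d", names(kept), kept), "")
    }
  }
  if (!is.null(results$cores)) {
    lines <- c(lines, "Core differential features per group:",
               sprintf("  %s: %d genes", names(results$cores),
                       lengths(results$cores)), "")
  }
  if (!is.null(results$enrichment)) {
    for (g in names(results$enrichment)) {
      sig <- results$enrichment[[g]]
      sig <- sig$set[sig$sig_05]
      if (length(sig))
        lines <- c(lines, sprintf("Enriched hallmark sets (q<0.05) in %s: %s",
                                  g, paste(sig, collapse = ", ")))
    }
    lines <- c(lines, "")
  }
  if (!is.null(results$survival)) {
    for (nm in names(results$survival$fits)) {
      f <- results$survival$fits[[nm]]
      lines <- c(lines, sprintf("Survival (%s), reference %s, logrank p = %.3g:",
                                nm, f$reference, f$logrank_p),
                 sprintf("  %s: HR %.2f [%.2f, %.2f], Wald p = %.3g (n=%d)",
                         f$estimates$level, f$estimates$hr, f$estimates$lower,
                         f$estimates$upper, f$estimates$wald_p, f$estimates$n))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
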