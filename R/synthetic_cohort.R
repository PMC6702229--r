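#' Configuration for the synthetic multi-omics cohort
#'
#' Bundles and validates every knob of the generator. The defaults emulate a
#' lung neuroendocrine cohort at desk scale: three molecular clusters with
#' distinct latent-factor means, a small "supra" group whose morphology label
#' disagrees with its molecular profile, a few intermediate samples that are
#' convex mixtures of two cluster profiles, cluster-dependent survival
#' hazards, cluster-enriched mutations, a subset of genes whose expression is
#' driven by promoter methylation, and a fraction of samples missing one omic
#' block entirely.
#'
#' @param n_samples total number of samples.
#' @param n_genes number of core genes (sex-linked and immune signature genes
#'   are generated in addition, with ids `gX*`, `gY*`, `IMM_*`).
#' @param n_cpgs number of CpG sites.
#' @param n_true_factors number of planted latent factors.
#' @param cluster_sizes named counts for the three pure clusters (A, B, C).
#' @param n_supra samples with cluster-B morphology label but cluster-C
#'   molecular profile.
#' @param n_intermediate samples mixing two cluster profiles.
#' @param cluster_factor_means cluster x factor matrix of latent means
#'   (arbitrary units; per-sample scores add standard normal noise).
#' @param loading_sparsity fraction of exactly-zero factor loadings.
#' @param nb_dispersion negative-binomial dispersion (1/size); 0 gives
#'   Poisson-like counts.
#' @param meth_noise_sd Gaussian noise sd on the methylation M-value scale.
#' @param library_size_range range of multiplicative library-size factors.
#' @param missing_block_fraction length-2 fractions of samples whose
#'   expression / methylation block is entirely absent (disjoint sets).
#' @param survival_log_hazards per-cluster log hazard (events per month).
#' @param censor_rate expected fraction of censored samples.
#' @param mutation_rates gene x cluster matrix of Bernoulli mutation
#'   probabilities; default built by [default_mutation_rates()].
#' @param n_methylation_driven_genes genes whose expression is suppressed by
#'   the M-value of a promoter CpG.
#' @param immune_fractions cluster x cell-type matrix of immune fractions
#'   (rows non-negative, sums <= 1); default built by
#'   [default_immune_fractions()].
#' @param seed integer seed; identical config + seed gives a byte-identical
#'   cohort.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 120L,
                       n_genes = 1000L,
                       n_cpgs = 800L,
                       n_true_factors = 3L,
                       cluster_sizes = c(A = 46L, B = 40L, C = 30L),
                       n_supra = 4L,
                       n_intermediate = 0L,
                       cluster_factor_means = NULL,
                       loading_sparsity = 0.7,
                       nb_dispersion = 0.1,
                       meth_noise_sd = 1,
                       library_size_range = c(0.7, 1.4),
                       missing_block_fraction = c(expression = 0.08,
                                                  methylation = 0.08),
                       survival_log_hazards = c(A = -4.8, B = -3.6, C = -2.6),
                       censor_rate = 0.3,
                       mutation_rates = NULL,
                       n_methylation_driven_genes = 50L,
                       immune_fractions = NULL,
                       seed = 1L) {
  if (is.null(cluster_factor_means)) {
    cluster_factor_means <- matrix(0, 3, n_true_factors,
                                   dimnames = list(c("A", "B", "C"), NULL))
    # factor 1 separates the high-grade cluster C; factor 2 separates A from B;
    # later factors carry no between-cluster signal.
    if (n_true_factors >= 1) cluster_factor_means[, 1] <- c(-2, -2, 3.5)
    if (n_true_factors >= 2) cluster_factor_means[, 2] <- c(-2.5, 2.5, 0)
  }
  if (is.null(mutation_rates)) mutation_rates <- default_mutation_rates()
  if (is.null(immune_fractions)) immune_fractions <- default_immune_fractions()

  cfg <- list(n_samples = as.integer(n_samples),
              n_genes = as.integer(n_genes), n_cpgs = as.integer(n_cpgs),
              n_true_factors = as.integer(n_true_factors),
              cluster_sizes = cluster_sizes, n_supra = as.integer(n_supra),
              n_intermediate = as.integer(n_intermediate),
              cluster_factor_means = cluster_factor_means,
              loading_sparsity = loading_sparsity,
              nb_dispersion = nb_dispersion, meth_noise_sd = meth_noise_sd,
              library_size_range = library_size_range,
              missing_block_fraction = missing_block_fraction,
              survival_log_hazards = survival_log_hazards,
              censor_rate = censor_rate, mutation_rates = mutation_rates,
              n_methylation_driven_genes = as.integer(n_methylation_driven_genes),
              immune_fractions = immune_fractions, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (length(cluster_sizes) != 3 || any(cluster_sizes < 0))
      stop("cluster_sizes must give three non-negative counts (A, B, C)")
    if (sum(cluster_sizes) + n_supra + n_intermediate != n_samples)
      stop("cluster_sizes + n_supra + n_intermediate must sum to n_samples")
    if (nrow(cluster_factor_means) != 3 ||
        ncol(cluster_factor_means) != n_true_factors)
      stop("cluster_factor_means must be 3 x n_true_factors")
    if (loading_sparsity < 0 || loading_sparsity > 1)
      stop("loading_sparsity must lie in [0, 1]")
    if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
    if (meth_noise_sd < 0) stop("meth_noise_sd must be >= 0")
    if (length(library_size_range) != 2 || any(library_size_range <= 0) ||
        diff(library_size_range) < 0)
      stop("library_size_range must be an increasing pair of positive reals")
    if (any(missing_block_fraction < 0) || sum(missing_block_fraction) >= 1)
      stop("missing_block_fraction entries must be >= 0 and sum < 1 so every sample keeps one block")
    if (censor_rate < 0 || censor_rate > 1) stop("censor_rate must lie in [0, 1]")
    if (any(mutation_rates < 0) || any(mutation_rates > 1))
      stop("mutation_rates must lie in [0, 1]")
    if (any(immune_fractions < 0) || any(rowSums(immune_fractions) > 1 + 1e-12))
      stop("immune_fractions rows must be non-negative with sum <= 1")
    if (n_methylation_driven_genes > min(n_genes, n_cpgs))
      stop("n_methylation_driven_genes exceeds available genes/CpGs")
  })
  invisible(cfg)
}

#' Default cluster-enriched mutation probabilities
#'
#' A small panel of genes recurrently mutated in lung neuroendocrine tumours,
#' with cluster-specific enrichment (e.g. TP53/RB1 in the high-grade cluster,
#' MEN1 in carcinoid cluster B, EIF1AX in cluster A) over a low background.
#'
#' @param n_background additional background genes mutated at rate 0.04.
#' @return gene x cluster (A, B, C) probability matrix.
#' @export
default_mutation_rates <- function(n_background = 16L) {
  planted <- rbind(
    EIF1AX  = c(0.35, 0.02, 0.02),
    MEN1    = c(0.05, 0.45, 0.05),
    ARID1A  = c(0.05, 0.30, 0.08),
    TP53    = c(0.02, 0.05, 0.60),
    RB1     = c(0.02, 0.02, 0.45),
    KMT2C   = c(0.10, 0.15, 0.10),
    SMARCA4 = c(0.03, 0.05, 0.20)
  )
  bg <- matrix(0.04, n_background, 3,
               dimnames = list(sprintf("mut_g%02d", seq_len(n_background)), NULL))
  m <- rbind(planted, bg)
  colnames(m) <- c("A", "B", "C")
  m
}

#' Default per-cluster immune-cell composition
#'
#' Ten immune cell types; rows are clusters, entries are expected fractions of
#' the bulk. Row sums are below 1, the remainder being tumour/stromal content.
#' @return 3 x 10 matrix.
#' @export
default_immune_fractions <- function() {
  types <- c("B_cells", "Macrophages_M1", "Macrophages_M2", "Monocytes",
             "Neutrophils", "NK_cells", "T_CD4", "T_CD8", "T_reg",
             "Dendritic_cells")
  m <- rbind(
    A = c(0.04, 0.03, 0.05, 0.04, 0.03, 0.02, 0.08, 0.06, 0.02, 0.03),
    B = c(0.03, 0.02, 0.06, 0.05, 0.10, 0.02, 0.06, 0.04, 0.03, 0.01),
    C = c(0.05, 0.05, 0.04, 0.03, 0.04, 0.04, 0.07, 0.09, 0.03, 0.02)
  )
  colnames(m) <- types
  m
}

#' Synthetic immune signature matrix
#'
#' Block-structured gene x cell-type reference: each cell type has six marker
#' genes with high expected expression and a low shared baseline. This is a
#' synthetic stand-in signature for testing the deconvolution machinery, not
#' a curated biological signature.
#'
#' @param markers_per_type marker genes per cell type.
#' @param baseline off-block expression level.
#' @return gene x cell-type numeric matrix.
#' @export
synthetic_immune_signature <- function(markers_per_type = 6L, baseline = 0.05) {
  types <- colnames(default_immune_fractions())
  n <- markers_per_type * length(types)
  S <- matrix(baseline, n, length(types),
              dimnames = list(character(n), types))
  for (j in seq_along(types)) {
    rows <- (j - 1) * markers_per_type + seq_len(markers_per_type)
    S[rows, j] <- 1 + 0.25 * seq_len(markers_per_type) / markers_per_type
    rownames(S)[rows] <- sprintf("IMM_%s_%d", types[j], seq_len(markers_per_type))
  }
  S
}

inv_m_value <- function(m) 1 / (1 + 2^(-m))

#' Generate a synthetic multi-omics cohort
#'
#' Draws a cohort with the planted structure described in [sim_config()]:
#' expression counts are negative binomial with log-mean = per-gene offset +
#' loadings x factor scores + log library size; methylation M-values are
#' loadings x scores + Gaussian noise, mapped to beta values by the inverse
#' M-transform (clamped to (1e-6, 1-1e-6)); survival times are exponential
#' with per-cluster log-hazards; a stated fraction of samples lacks one omic
#' block (absent columns, not NA cells).
#'
#' @param config a [sim_config()] object.
#' @return an object of class `nen_cohort`: a list with elements
#'   `expression` (genes x samples integer counts), `methylation`
#'   (CpGs x samples beta values), `clinical` (data frame), `mutations`
#'   (genes x samples 0/1), `annotation` (feature positions), `truth`
#'   (planted labels, factor scores, immune fractions) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_samples
  K <- config$n_true_factors
  sizes <- config$cluster_sizes
  clusters <- c("A", "B", "C")

  sample_type <- c(rep("pure", sum(sizes)), rep("supra", config$n_supra),
                   rep("intermediate", config$n_intermediate))
  molecular <- c(rep(clusters, times = sizes),
                 rep("C", config$n_supra),      # supra: high-grade profile
                 rep("A", config$n_intermediate))
  # intermediate samples: morphology calls alternate between the two mixed
  # clusters, as morphologically ambiguous cases draw inconsistent labels
  morphology <- c(rep(clusters, times = sizes),
                  rep("B", config$n_supra),     # ... under carcinoid-B morphology
                  rep(c("A", "B"), length.out = config$n_intermediate))
  sample_id <- sprintf("S%03d", seq_len(n))

  # latent factor scores: cluster mean + unit noise; intermediates mix A and B
  mu_z <- config$cluster_factor_means[molecular, , drop = FALSE]
  mix_weight <- rep(NA_real_, n)
  inter <- which(sample_type == "intermediate")
  if (length(inter)) {
    lambda <- stats::runif(length(inter), 0.35, 0.5)   # weight on cluster B
    mix_weight[inter] <- lambda
    mu_z[inter, ] <- (1 - lambda) %o% config$cluster_factor_means["A", ] +
      lambda %o% config$cluster_factor_means["B", ]
  }
  Z <- mu_z + matrix(stats::rnorm(n * K), n, K)
  rownames(Z) <- sample_id
  colnames(Z) <- paste0("LF", seq_len(K))

  # --- expression block -----------------------------------------------------
  g_core <- sprintf("g%04d", seq_len(config$n_genes))
  g_x <- sprintf("gX%02d", 1:10)
  g_y <- sprintf("gY%02d", 1:10)
  sig <- synthetic_immune_signature()
  genes <- c(g_core, g_x, g_y, rownames(sig))

  W_e <- matrix(stats::rnorm(config$n_genes * K, sd = 0.4), config$n_genes, K)
  W_e[matrix(stats::runif(length(W_e)) < config$loading_sparsity,
             nrow(W_e))] <- 0
  rownames(W_e) <- g_core

  offset <- stats::runif(config$n_genes, log(5), log(300))
  libsize <- stats::runif(n, config$library_size_range[1],
                          config$library_size_range[2])

  # --- methylation block ----------------------------------------------------
  cpgs <- sprintf("cg%05d", seq_len(config$n_cpgs))
  W_m <- matrix(stats::rnorm(config$n_cpgs * K, sd = 0.4), config$n_cpgs, K)
  W_m[matrix(stats::runif(length(W_m)) < config$loading_sparsity,
             nrow(W_m))] <- 0
  n_mdg <- config$n_methylation_driven_genes
  if (n_mdg > 0) {
    # driven CpGs must carry factor signal so the coupled genes do too
    W_m[seq_len(n_mdg), ] <- matrix(
      stats::rnorm(n_mdg * K, sd = 0.6), n_mdg, K)
  }
  m_off <- stats::rnorm(config$n_cpgs, 0, 1.5)
  M <- m_off + W_m %*% t(Z) +
    matrix(stats::rnorm(config$n_cpgs * n, sd = config$meth_noise_sd),
           config$n_cpgs, n)
  beta <- inv_m_value(M)
  beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
  dimnames(beta) <- list(cpgs, sample_id)

  # expression log-mean; methylation-driven genes are suppressed by their
  # promoter CpG's M-value
  logmu <- offset + W_e %*% t(Z)
  if (n_mdg > 0) {
    Mc <- M[seq_len(n_mdg), , drop = FALSE]
    logmu[seq_len(n_mdg), ] <- offset[seq_len(n_mdg)] -
      0.7 * (Mc - rowMeans(Mc))
  }
  mu_core <- exp(logmu) * rep(libsize, each = config$n_genes)

  # sex, needed for the sex-linked genes
  sex <- ifelse(stats::runif(n) < ifelse(molecular == "B", 0.75, 0.5),
                "M", "F")
  mu_x <- matrix(exp(stats::runif(10, log(20), log(80))), 10, n) *
    rep(ifelse(sex == "F", 1.4, 1.0), each = 10) *
    rep(libsize, each = 10)
  mu_y <- matrix(exp(stats::runif(10, log(20), log(80))), 10, n) *
    rep(ifelse(sex == "M", 1.0, 0.01), each = 10) *
    rep(libsize, each = 10)

  # immune signature genes: linear mixture of the signature at the sample's
  # immune fractions (supra samples: dendritic-cell rich, as a planted contrast)
  frac <- config$immune_fractions[molecular, , drop = FALSE]
  supra <- which(sample_type == "supra")
  if (length(supra)) frac[supra, "Dendritic_cells"] <- 0.15
  frac <- frac * matrix(stats::runif(length(frac), 0.8, 1.2), nrow(frac))
  frac <- frac / pmax(1, rowSums(frac) / 0.95)   # keep row sums < 1
  rownames(frac) <- sample_id
  mu_imm <- 60 * (sig %*% t(frac)) * rep(libsize, each = nrow(sig))

  mu <- rbind(mu_core, mu_x, mu_y, mu_imm)
  size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf
  counts <- matrix(
    if (is.finite(size)) stats::rnbinom(length(mu), mu = mu, size = size)
    else stats::rpois(length(mu), lambda = mu),
    nrow(mu))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(genes, sample_id)

  # --- mutations ------------------------------------------------------------
  rates <- config$mutation_rates[, molecular, drop = FALSE]
  mut <- matrix(as.integer(stats::runif(length(rates)) < rates),
                nrow = nrow(rates), ncol = n)
  dimnames(mut) <- list(rownames(config$mutation_rates), sample_id)

  # --- survival / clinical --------------------------------------------------
  rate <- exp(config$survival_log_hazards[molecular])
  t_true <- stats::rexp(n, rate)
  censored <- stats::runif(n) < config$censor_rate
  os <- ifelse(censored, stats::runif(n) * t_true, t_true)
  clinical <- data.frame(
    sample_id = sample_id,
    histology = c(A = "Typical", B = "Atypical", C = "LCNEC")[morphology],
    sex = sex,
    age_class = sample(c("(16,40]", "(40,60]", "(60,90]"), n, TRUE,
                       prob = c(0.2, 0.4, 0.4)),
    stage = sample(c("I", "II", "III", "IV"), n, TRUE,
                   prob = c(0.4, 0.3, 0.2, 0.1)),
    smoking = sample(c("never", "former", "current"), n, TRUE),
    batch = sample(c("P1", "P2", "P3"), n, TRUE),
    os_months = os,
    os_event = as.integer(!censored),
    stringsAsFactors = FALSE)

  # --- annotation -----------------------------------------------------------
  gene_chrom <- c(sample(paste0("chr", 1:22), config$n_genes, TRUE),
                  rep("chrX", 10), rep("chrY", 10),
                  sample(paste0("chr", 1:22), nrow(sig), TRUE))
  gene_tss <- sample.int(1e8, length(genes))
  cpg_chrom <- sample(paste0("chr", 1:22), config$n_cpgs, TRUE)
  cpg_pos <- sample.int(1e8, config$n_cpgs)
  if (n_mdg > 0) {   # driven CpG i sits in the promoter window of gene i
    cpg_chrom[seq_len(n_mdg)] <- gene_chrom[seq_len(n_mdg)]
    cpg_pos[seq_len(n_mdg)] <- gene_tss[seq_len(n_mdg)] +
      sample(-1800:1800, n_mdg, TRUE)
  }
  annotation <- data.frame(
    feature = c(genes, cpgs),
    type = c(rep("gene", length(genes)), rep("cpg", length(cpgs))),
    chrom = c(gene_chrom, cpg_chrom),
    pos = c(gene_tss, cpg_pos),
    strand = "+",
    stringsAsFactors = FALSE)

  # --- missing blocks (absent sample columns, disjoint across blocks) -------
  n_miss_e <- floor(config$missing_block_fraction[1] * n)
  n_miss_m <- floor(config$missing_block_fraction[2] * n)
  miss <- sample(sample_id, n_miss_e + n_miss_m)
  miss_e <- miss[seq_len(n_miss_e)]
  miss_m <- setdiff(miss, miss_e)
  counts <- counts[, setdiff(sample_id, miss_e), drop = FALSE]
  beta <- beta[, setdiff(sample_id, miss_m), drop = FALSE]

  truth <- data.frame(sample_id = sample_id, cluster = molecular,
                      morphology = morphology, sample_type = sample_type,
                      mix_weight = mix_weight, stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(Z),
                 as.data.frame(frac, optional = TRUE))

  structure(list(expression = counts, methylation = beta,
                 clinical = clinical, mutations = mut,
                 annotation = annotation, truth = truth,
                 signature = sig, config = config),
            class = "nen_cohort")
}

#' @export
print.nen_cohort <- function(x, ...) {
  cat("Synthetic multi-omics cohort\n")
  cat(sprintf("  samples: %d (expression: %d, methylation: %d)\n",
              nrow(x$clinical), ncol(x$expression), ncol(x$methylation)))
  cat(sprintf("  genes: %d, CpGs: %d, mutation genes: %d\n",
              nrow(x$expression), nrow(x$methylation), nrow(x$mutations)))
  cat("  planted clusters:",
      paste(names(table(x$truth$cluster)), table(x$truth$cluster),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a cohort to a directory of TSV files
#'
#' Emits `expression.tsv`, `methylation.tsv`, `clinical.tsv`, `mutations.tsv`,
#' `annotation.tsv`, `truth.tsv` and a `manifest.yaml` recording the seed and
#' configuration. Numeric values are written at full double precision so
#' [read_cohort()] reproduces the cohort exactly.
#'
#' @param cohort an `nen_cohort`.
#' @param directory output directory (created if absent).
#' @return `directory`, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "nen_cohort"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (file.access(directory, 2) != 0) stop("directory not writable: ", directory)
  write_matrix_tsv(cohort$expression, file.path(directory, "expression.tsv"))
  write_matrix_tsv(cohort$methylation, file.path(directory, "methylation.tsv"))
  write_matrix_tsv(cohort$mutations, file.path(directory, "mutations.tsv"))
  write_df_tsv(cohort$clinical, file.path(directory, "clinical.tsv"))
  write_df_tsv(cohort$annotation, file.path(directory, "annotation.tsv"))
  write_df_tsv(cohort$truth, file.path(directory, "truth.tsv"))
  write_matrix_tsv(cohort$signature, file.path(directory, "signature.tsv"))
  cfg <- cohort$config
  cfg_plain <- lapply(unclass(cfg), function(v)
    if (is.matrix(v)) list(dim = dim(v), dimnames = dimnames(v),
                           values = as.numeric(v)) else v)
  yaml::write_yaml(cfg_plain, file.path(directory, "manifest.yaml"))
  invisible(directory)
}

#' Read a cohort written by [write_cohort()]
#' @param directory directory containing the TSV files.
#' @return an `nen_cohort`.
#' @export
read_cohort <- function(directory) {
  read_df <- function(f) utils::read.delim(file.path(directory, f),
                                           stringsAsFactors = FALSE)
  cfg_plain <- yaml::read_yaml(file.path(directory, "manifest.yaml"))
  cfg <- lapply(cfg_plain, function(v) {
    if (is.list(v) && !is.null(v$dim)) {
      m <- matrix(unlist(v$values) %||% numeric(0), v$dim[[1]], v$dim[[2]])
      dimnames(m) <- lapply(v$dimnames, unlist)
      m
    } else if (is.list(v)) unlist(v) else v
  })
  class(cfg) <- "sim_config"
  mut <- read_matrix_tsv(file.path(directory, "mutations.tsv"))
  storage.mode(mut) <- "integer"
  expr <- read_matrix_tsv(file.path(directory, "expression.tsv"))
  storage.mode(expr) <- "integer"
  structure(list(
    expression = expr,
    methylation = read_matrix_tsv(file.path(directory, "methylation.tsv")),
    clinical = read_df("clinical.tsv"),
    mutations = mut,
    annotation = read_df("annotation.tsv"),
    truth = read_df("truth.tsv"),
    signature = read_matrix_tsv(file.path(directory, "signature.tsv")),
    config = cfg), class = "nen_cohort")
}
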