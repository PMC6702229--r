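#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted Rand index, used to compare recovered cluster
#' labels with a reference partition. 1 means identical partitions (up to
#' label permutation), 0 is the expectation under independent random
#' partitions.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return a single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated, fields = set name,
#' description, then member ids.
#'
#' @param path path to a .gmt file.
#' @return named list of character vectors of member ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Write a GMT gene-set file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector, recycled.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descriptions <- rep_len(descriptions, length(sets))
  lines <- mapply(function(nm, d, members)
    paste(c(nm, d, members), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

# Full-precision TSV writers: numeric values are serialised with %.17g so a
# write/read round trip reproduces doubles exactly.
write_matrix_tsv <- function(m, path) {
  df <- as.data.frame(m, check.names = FALSE)
  out <- vapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  }, character(nrow(df)))
  out <- matrix(out, nrow = nrow(df))
  header <- paste(c("feature", colnames(m)), collapse = "\t")
  body <- if (nrow(df) > 0)
    paste(rownames(m), apply(out, 1, paste, collapse = "\t"), sep = "\t")
  else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    return(matrix(numeric(0), nrow = 0, ncol = ncol(df) - 1,
                  dimnames = list(NULL, colnames(df)[-1])))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

write_df_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Derive a per-stage seed from a global seed and a stage name, so stages can
# be rerun independently but reproducibly. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435L + h * 97L) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
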