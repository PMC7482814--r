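#' @useDynLib tandemAPA, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median sd cor quantile rnorm runif rmultinom kmeans hclust
#'   cutree cophenetic as.dist pbeta pt wilcox.test ks.test var dist ave
#' @importFrom utils read.delim write.table
NULL

#' Derive a child seed from a global seed and a stage label
#'
#' All stochastic stages (simulators, MCMC, NMF restarts, consensus resampling)
#' draw their seed from the single global seed through this counter-based
#' scheme, so each stage is independently reproducible.
#'
#' @param seed integer global seed.
#' @param stage character stage label (e.g. `"bcp"`, `"nmf"`).
#' @param index optional integer counter for repeated calls within a stage.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  x <- (as.double(seed) * 69069 + h * 1013 + as.double(index) * 7919) %% 2147483646
  as.integer(x) + 1L
}

#' Write a numeric matrix as TSV with row identifiers
#'
#' @param x numeric matrix with rownames and colnames.
#' @param file output path.
#' @param id_name header for the row-identifier column.
#' @export
write_matrix_tsv <- function(x, file, id_name = "id") {
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_name, colnames(x))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a TSV matrix written by [write_matrix_tsv()]
#'
#' @param file input path; first column holds row identifiers.
#' @return numeric matrix. Missing values are an error: probe-level analysis
#'   requires complete intensities.
#' @export
read_matrix_tsv <- function(file) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (anyNA(m) || any(!is.finite(m))) {
    stop("matrix in '", file, "' contains missing or non-finite values")
  }
  m
}

#' Percentage table from category counts
#'
#' Reporting utility used for cohort summaries: converts a named vector of
#' counts into percentages of the total, rounded to one decimal place (the
#' convention used in clinical characteristics tables).
#'
#' @param counts named non-negative integer vector.
#' @param total denominator; defaults to `sum(counts)`.
#' @return named numeric vector of percentages.
#' @export
proportion_table <- function(counts, total = sum(counts)) {
  stopifnot(all(counts >= 0), total > 0)
  round(100 * counts / total, 1)
}
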