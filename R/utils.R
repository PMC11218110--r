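#' Evaluate an expression with a local RNG seed
#'
#' All randomness in the package flows through explicit integer seeds; the
#' caller's RNG state is untouched.
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

#' Fisher's method for combining p-values
#'
#' Combines a vector of independent two-sided p-values into one via
#' -2 * sum(log p) ~ chi-square with 2k degrees of freedom. Zeros are clamped
#' to the smallest positive double so a single perfect correlation does not
#' produce NaN.
#'
#' @param p numeric vector of p-values in \[0, 1\]
#' @return combined p-value
#' @export
fisher_combine <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) return(NA_real_)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  stat <- -2 * sum(log(p))
  stats::pchisq(stat, df = 2 * length(p), lower.tail = FALSE)
}

#' Adjusted Rand Index between two labelings
#'
#' Standard permutation-model-adjusted Rand index computed from the
#' contingency table of the two partitions. 1 means identical partitions,
#' 0 is the chance expectation.
#'
#' @param a,b label vectors of equal length
#' @return numeric ARI
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

#' Cluster purity against known class labels
#'
#' Fraction of samples assigned to the majority class of their cluster.
#'
#' @param clusters cluster assignments
#' @param classes true class labels
#' @return purity in \[0, 1\]
#' @export
cluster_purity <- function(clusters, classes) {
  stopifnot(length(clusters) == length(classes))
  tab <- table(clusters, classes)
  sum(apply(tab, 1, max)) / length(clusters)
}

# row variances for a numeric matrix (two-pass, stable enough here)
row_vars <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

# validated genes-by-samples expression matrix with a unit tag
expression_matrix <- function(mat, unit = c("counts", "FPKM", "normalized", "log2")) {
  unit <- match.arg(unit)
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression matrix needs gene rownames and sample colnames")
  attr(mat, "unit") <- unit
  mat
}

expr_unit <- function(mat) attr(mat, "unit") %||% "unknown"

`%||%` <- function(a, b) if (is.null(a)) b else a
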