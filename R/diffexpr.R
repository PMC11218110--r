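#' Median-of-ratios count normalization
#'
#' Per-sample size factors are the median, across genes, of the ratio of the
#' sample's count to the gene's geometric mean over all samples; genes with
#' any zero count are excluded from factor estimation. Factors are rescaled
#' to geometric mean 1 (they are only defined up to a common scale), which
#' makes normalization idempotent, and counts are divided by them.
#'
#' @param counts genes x samples matrix of non-negative counts (>= 2 samples)
#' @return normalized matrix (unit "normalized") with attribute
#'   `size_factors`
#' @export
normalize_counts <- function(counts) {
  if (ncol(counts) < 2) stop("need at least 2 samples to normalize")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (all(counts == 0)) stop("all-zero count matrix cannot be normalized")
  usable <- rowSums(counts == 0) == 0
  if (!any(usable))
    stop("every gene contains a zero; size factors cannot be estimated")
  use <- counts[usable, , drop = FALSE]
  geo <- exp(rowMeans(log(use)))
  sf <- apply(use, 2, function(x) stats::median(x / geo))
  sf <- sf / exp(mean(log(sf)))
  norm <- sweep(counts, 2, sf, "/")
  norm <- expression_matrix(norm, "normalized")
  attr(norm, "size_factors") <- sf
  norm
}

#' Differential-expression test with fold-change and FDR thresholds
#'
#' Per-gene Welch t-tests (unpaired) or paired t-tests on
#' log2(normalized + pseudocount), with Benjamini-Hochberg adjustment over
#' all tested genes. A gene is significant when its signed fold change
#' strictly exceeds `fc_threshold` or is strictly below `-fc_threshold`
#' AND its FDR-adjusted p is strictly below `alpha` — both conditions
#' required, matching the DEG definition used for blood samples
#' (fc_threshold 2) and cell lines (fc_threshold 1.2).
#'
#' The signed fold change is mean_B / mean_A when >= 1 and
#' -mean_A / mean_B otherwise, so fold change -2 means B is at half the
#' level of A. Means are taken on the normalized scale without pseudocount,
#' floored at `mean_floor` to avoid division by zero. Genes constant across
#' both groups get p = 1 and are flagged, not dropped.
#'
#' @param expr genes x samples normalized matrix (see [normalize_counts()]);
#'   any non-negative expression matrix is accepted
#' @param meta data.frame with `sample` and grouping (and pairing) columns
#' @param contrast `c(groupA, groupB)`; fold changes are B relative to A
#' @param group_col,pair_col metadata column names
#' @param paired paired t-test on within-pair log2 differences
#' @param fc_threshold absolute signed fold-change threshold (strict)
#' @param alpha FDR threshold (strict)
#' @param pseudocount added before log2 for testing
#' @param mean_floor floor applied to group means in the fold-change ratio
#' @return object of class `deg_table`: data.frame with gene, mean_A,
#'   mean_B, fold_change, log2fc, t, p_raw, p_fdr, significant, constant
#' @export
de_test <- function(expr, meta, contrast, group_col = "group",
                    pair_col = "pair_id", paired = FALSE, fc_threshold = 2,
                    alpha = 0.05, pseudocount = 1, mean_floor = 1e-8) {
  stopifnot(length(contrast) == 2, "sample" %in% names(meta))
  meta <- meta[match(colnames(expr), meta$sample), , drop = FALSE]
  grp <- meta[[group_col]]
  a_idx <- which(grp == contrast[1])
  b_idx <- which(grp == contrast[2])
  if (length(a_idx) < 2 || length(b_idx) < 2)
    stop("both groups need at least 2 samples")

  L <- log2(expr + pseudocount)
  A <- L[, a_idx, drop = FALSE]
  B <- L[, b_idx, drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)

  if (paired) {
    pa <- meta[[pair_col]][a_idx]
    pb <- meta[[pair_col]][b_idx]
    orphans <- c(setdiff(pa, pb), setdiff(pb, pa))
    if (length(orphans) > 0 || anyNA(c(pa, pb)))
      stop("paired mode requires matched pairs; orphans: ",
           paste(unique(stats::na.omit(orphans)), collapse = ", "))
    D <- B[, order(pb), drop = FALSE] - A[, order(pa), drop = FALSE]
    n <- ncol(D)
    md <- rowMeans(D)
    sd_d <- sqrt(row_vars(D))
    tstat <- md / (sd_d / sqrt(n))
    df <- rep(n - 1, nrow(D))
  } else {
    mA <- rowMeans(A); mB <- rowMeans(B)
    vA <- row_vars(A); vB <- row_vars(B)
    se2 <- vA / nA + vB / nB
    tstat <- (mB - mA) / sqrt(se2)
    df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  }
  p_raw <- 2 * stats::pt(-abs(tstat), df = df)
  # zero-variance genes: 0/0 gives NaN; equal means -> null (p = 1), and a
  # zero-variance nonzero difference already yields t = +/-Inf, p = 0
  constant <- is.nan(tstat)
  p_raw[constant] <- 1
  tstat[constant] <- 0
  p_raw[is.infinite(tstat)] <- 0

  mean_A <- rowMeans(expr[, a_idx, drop = FALSE])
  mean_B <- rowMeans(expr[, b_idx, drop = FALSE])
  ratio <- pmax(mean_B, mean_floor) / pmax(mean_A, mean_floor)
  fold_change <- ifelse(ratio >= 1, ratio, -1 / ratio)
  log2fc <- log2(ratio)

  p_fdr <- stats::p.adjust(p_raw, method = "BH")
  significant <- (fold_change > fc_threshold | fold_change < -fc_threshold) &
    p_fdr < alpha

  out <- data.frame(gene = rownames(expr), mean_A = mean_A, mean_B = mean_B,
                    fold_change = fold_change, log2fc = log2fc, t = tstat,
                    p_raw = p_raw, p_fdr = p_fdr, significant = significant,
                    constant = constant, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("deg_table", "data.frame"),
            contrast = contrast, paired = paired,
            fc_threshold = fc_threshold, alpha = alpha)
}

#' Significant genes of a DEG table
#'
#' @param tab a `deg_table`
#' @return character vector of significant gene IDs
#' @export
significant_genes <- function(tab) {
  stopifnot(is.data.frame(tab), all(c("gene", "significant") %in% names(tab)))
  tab$gene[tab$significant]
}

#' Common/Unique DEG set algebra across contrasts
#'
#' Given two or more DEG tables (or plain character sets of significant
#' genes), computes the genes significant in every contrast (`common`) and,
#' per contrast, the genes significant in that contrast only
#' (`unique_<name>` = its set minus the union of all others).
#'
#' @param tables named list of `deg_table`s or character vectors
#' @return object of class `deg_sets`: list with `common`, `unique` (named
#'   list), `sets` (the input significant sets) and `counts`
#' @export
deg_set_algebra <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 2, !is.null(names(tables)))
  sets <- lapply(tables, function(x)
    if (is.character(x)) unique(x) else significant_genes(x))
  common <- Reduce(intersect, sets)
  uniq <- lapply(seq_along(sets), function(i)
    setdiff(sets[[i]], Reduce(union, sets[-i])))
  names(uniq) <- names(sets)
  counts <- c(common = length(common),
              stats::setNames(lengths(uniq), paste0("unique_", names(uniq))))
  structure(list(common = common, unique = uniq, sets = sets,
                 counts = counts), class = "deg_sets")
}

#' Stratify samples by hierarchical clustering on a DEG set
#'
#' Expression of the given genes is log2(x + 1)-transformed and z-scored per
#' gene; samples are clustered agglomeratively (average linkage by default)
#' on correlation distance (1 - Pearson between sample profiles). When true
#' labels are supplied, the Adjusted Rand Index and cluster purity of the
#' cut are reported.
#'
#' @param expr genes x samples matrix (normalized or FPKM scale)
#' @param genes gene set to cluster on (>= 2 genes, all present)
#' @param k number of clusters to cut
#' @param true_labels optional known labels per sample (in column order)
#' @param linkage hclust agglomeration method
#' @param distance "correlation" (1 - Pearson) or "euclidean"
#' @param log_transform apply log2(x + 1) before z-scoring (set FALSE if
#'   `expr` is already on log scale)
#' @return list with `labels` (named cluster assignments), `hclust`, and
#'   when true labels are given, `ari` and `purity`
#' @export
stratify_by_degs <- function(expr, genes, k = 2, true_labels = NULL,
                             linkage = "average",
                             distance = c("correlation", "euclidean"),
                             log_transform = TRUE) {
  distance <- match.arg(distance)
  if (length(genes) < 2) stop("need at least 2 genes to cluster on")
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0)
    stop("gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  X <- expr[genes, , drop = FALSE]
  if (log_transform) X <- log2(X + 1)
  v <- row_vars(X)
  if (any(v == 0)) {
    warning(sum(v == 0), " constant gene(s) dropped before z-scoring")
    X <- X[v > 0, , drop = FALSE]
    if (nrow(X) < 2) stop("fewer than 2 non-constant genes remain")
  }
  Z <- t(scale(t(X)))
  d <- if (distance == "correlation") stats::as.dist(1 - stats::cor(Z))
       else stats::dist(t(Z))
  hc <- stats::hclust(d, method = linkage)
  labels <- stats::cutree(hc, k = k)
  out <- list(labels = labels, hclust = hc)
  if (!is.null(true_labels)) {
    stopifnot(length(true_labels) == ncol(expr))
    out$ari <- adjusted_rand_index(labels, true_labels)
    out$purity <- cluster_purity(labels, true_labels)
  }
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' Computes 2^-((ct_target - ct_reference) - (ct_target_cal -
#' ct_reference_cal)): the target gene's expression relative to a reference
#' gene, calibrated against a control sample. Vectorized over all arguments.
#'
#' @param ct_target,ct_reference Ct values in the sample of interest
#' @param ct_target_cal,ct_reference_cal Ct values in the calibrator sample
#' @return relative expression (1 = no change)
#' @export
ddct <- function(ct_target, ct_reference, ct_target_cal, ct_reference_cal) {
  stopifnot(all(is.finite(c(ct_target, ct_reference,
                            ct_target_cal, ct_reference_cal))))
  2^-((ct_target - ct_reference) - (ct_target_cal - ct_reference_cal))
}
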