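#' Select final marker genes by within-subset pairwise correlation
#'
#' For each cell subset, Pearson correlation is computed between every pair
#' of candidate marker genes across samples on log2(FPKM + pseudocount). A
#' gene's `avg_r` is the mean of its pairwise correlations with the other
#' candidates of the same subset; its `combined_p` is the Fisher combination
#' of the two-sided p-values of those correlations (t transformation, n - 2
#' degrees of freedom). Genes are retained when `avg_r` strictly exceeds
#' `r_threshold` and `combined_p` is strictly below `p_threshold`; if more
#' than `max_k` pass, the top `max_k` by `avg_r` are kept (ties broken
#' alphabetically by gene ID), and a warning is emitted when fewer than
#' `min_k` pass.
#'
#' The defaults (r > 0.60, p < 0.01, 10-20 final markers) reproduce the
#' marker-filtering criteria of the blood deconvolution procedure this
#' package implements.
#'
#' @param expr genes x samples FPKM matrix (>= 3 samples)
#' @param candidates named list: subset -> candidate gene IDs
#' @param r_threshold minimum average pairwise Pearson r (strict)
#' @param p_threshold maximum Fisher-combined p (strict)
#' @param min_k,max_k target band for the retained panel size
#' @param pseudocount added before log2
#' @return object of class `marker_panel`: data.frame with columns subset,
#'   gene, avg_r, combined_p, retained
#' @export
select_markers <- function(expr, candidates, r_threshold = 0.60,
                           p_threshold = 0.01, min_k = 10, max_k = 20,
                           pseudocount = 1) {
  stopifnot(is.list(candidates), length(candidates) >= 1,
            !is.null(names(candidates)))
  if (ncol(expr) < 3)
    stop("at least 3 samples are required to compute correlation p-values")
  missing <- setdiff(unlist(candidates), rownames(expr))
  if (length(missing) > 0)
    stop("candidate gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))

  n <- ncol(expr)
  L <- log2(expr + pseudocount)
  out <- list()
  for (subset in names(candidates)) {
    genes <- candidates[[subset]]
    if (length(genes) < 2)
      stop("subset ", subset, " needs at least 2 candidate genes")
    C <- stats::cor(t(L[genes, , drop = FALSE]))
    tstat <- C * sqrt((n - 2) / pmax(1 - C^2, 0))
    P <- 2 * stats::pt(-abs(tstat), df = n - 2)
    avg_r <- vapply(seq_along(genes), function(i) mean(C[i, -i]), numeric(1))
    comb_p <- vapply(seq_along(genes), function(i) fisher_combine(P[i, -i]),
                     numeric(1))
    pass <- avg_r > r_threshold & comb_p < p_threshold
    retained <- pass
    if (sum(pass) > max_k) {
      idx <- which(pass)
      ord <- idx[order(-avg_r[idx], genes[idx])]
      retained[] <- FALSE
      retained[ord[seq_len(max_k)]] <- TRUE
    } else if (sum(pass) < min_k) {
      warning("subset ", subset, ": only ", sum(pass),
              " markers pass the filter (target band ", min_k, "-", max_k, ")")
    }
    out[[subset]] <- data.frame(subset = subset, gene = genes,
                                avg_r = avg_r, combined_p = comb_p,
                                retained = retained,
                                stringsAsFactors = FALSE)
  }
  panel <- do.call(rbind, out)
  rownames(panel) <- NULL
  structure(panel, class = c("marker_panel", "data.frame"),
            r_threshold = r_threshold, p_threshold = p_threshold,
            min_k = min_k, max_k = max_k)
}

#' Retained markers of a panel as a named list
#'
#' @param panel a `marker_panel`
#' @return named list subset -> retained gene IDs
#' @export
retained_markers <- function(panel) {
  stopifnot(inherits(panel, "marker_panel"))
  kept <- panel[panel$retained, , drop = FALSE]
  split(kept$gene, factor(kept$subset, levels = unique(panel$subset)))
}

#' Raw cell-abundance scores from a marker panel
#'
#' The abundance score of a subset in a sample is the simple average of the
#' retained marker genes' log2(FPKM + pseudocount). Scores are in log2
#' expression units and are comparable across samples within one panel.
#'
#' @param expr genes x samples FPKM matrix
#' @param panel a `marker_panel` with retained markers present in `expr`
#' @param pseudocount added before log2 (default 1, so FPKM 0 scores 0)
#' @return samples x subsets numeric matrix with attribute `pseudocount`
#' @export
abundance_scores <- function(expr, panel, pseudocount = 1) {
  markers <- retained_markers(panel)
  empty <- names(markers)[lengths(markers) == 0]
  if (length(empty) > 0)
    stop("no retained markers for subset(s): ", paste(empty, collapse = ", "))
  missing <- setdiff(unlist(markers), rownames(expr))
  if (length(missing) > 0)
    stop("retained marker(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  L <- log2(expr + pseudocount)
  scores <- vapply(markers, function(g)
    colMeans(L[g, , drop = FALSE]), numeric(ncol(expr)))
  scores <- matrix(scores, nrow = ncol(expr),
                   dimnames = list(colnames(expr), names(markers)))
  attr(scores, "pseudocount") <- pseudocount
  scores
}

#' Compare abundance scores between two groups, per subset
#'
#' Independent (Welch) t-tests, or paired t-tests when `paired = TRUE` and
#' complete pair IDs are available in both groups. The reported mean
#' difference is group B minus group A for `contrast = c(A, B)`. When paired
#' differences have zero variance the t statistic is undefined; a two-sided
#' exact sign test on the non-zero differences is reported instead, with a
#' warning.
#'
#' @param scores samples x subsets matrix from [abundance_scores()]
#' @param meta data.frame with a `sample` column matching rownames of
#'   `scores`, plus the grouping and pairing columns
#' @param contrast length-2 character vector `c(groupA, groupB)`
#' @param paired use paired t-tests
#' @param group_col,pair_col metadata column names
#' @return data.frame with subset, n_A, n_B, mean_diff, t, p, method
#' @export
compare_scores <- function(scores, meta, contrast, paired = FALSE,
                           group_col = "group", pair_col = "pair_id") {
  stopifnot(length(contrast) == 2, "sample" %in% names(meta),
            group_col %in% names(meta))
  meta <- meta[match(rownames(scores), meta$sample), , drop = FALSE]
  if (anyNA(meta$sample))
    stop("metadata is missing entries for some score rows")
  grp <- meta[[group_col]]
  a_idx <- which(grp == contrast[1])
  b_idx <- which(grp == contrast[2])
  if (length(a_idx) < 2 || length(b_idx) < 2)
    stop("both contrast groups need at least 2 samples")

  if (paired) {
    if (!pair_col %in% names(meta)) stop("pairing column not found: ", pair_col)
    pa <- meta[[pair_col]][a_idx]
    pb <- meta[[pair_col]][b_idx]
    orphans <- c(setdiff(pa, pb), setdiff(pb, pa))
    if (length(orphans) > 0 || anyNA(c(pa, pb)))
      stop("paired mode requires matched pairs in both groups; orphans: ",
           paste(unique(stats::na.omit(orphans)), collapse = ", "))
    a_idx <- a_idx[order(pa)]
    b_idx <- b_idx[order(pb)]
  }

  res <- lapply(colnames(scores), function(subset) {
    a <- scores[a_idx, subset]
    b <- scores[b_idx, subset]
    if (paired) {
      d <- b - a
      if (stats::var(d) == 0) {
        nz <- d[d != 0]
        p <- if (length(nz) == 0) 1
             else stats::binom.test(sum(nz > 0), length(nz))$p.value
        warning("subset ", subset,
                ": zero-variance paired differences; sign-test p reported")
        return(data.frame(subset = subset, n_A = length(a), n_B = length(b),
                          mean_diff = mean(d), t = NA_real_, p = p,
                          method = "sign", stringsAsFactors = FALSE))
      }
      tt <- stats::t.test(d)
      return(data.frame(subset = subset, n_A = length(a), n_B = length(b),
                        mean_diff = mean(d), t = unname(tt$statistic),
                        p = tt$p.value, method = "paired_t",
                        stringsAsFactors = FALSE))
    }
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      eq <- isTRUE(all.equal(mean(a), mean(b)))
      return(data.frame(subset = subset, n_A = length(a), n_B = length(b),
                        mean_diff = mean(b) - mean(a),
                        t = if (eq) 0 else sign(mean(b) - mean(a)) * Inf,
                        p = if (eq) 1 else 0, method = "welch_t",
                        stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(b, a)
    data.frame(subset = subset, n_A = length(a), n_B = length(b),
               mean_diff = mean(b) - mean(a), t = unname(tt$statistic),
               p = tt$p.value, method = "welch_t", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
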