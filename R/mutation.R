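#' Keep only PASS variants
#'
#' Retains records whose FILTER equals the literal string "PASS"; everything
#' else, including "." (no filter applied), is dropped. The number of
#' removed records is reported via [message()].
#'
#' @param variants data.frame with at least a `filter` column
#' @return the PASS subset, same columns
#' @export
filter_pass <- function(variants) {
  stopifnot("filter" %in% names(variants))
  keep <- variants$filter == "PASS"
  message(sum(!keep), " non-PASS variant record(s) removed")
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank mutated genes by driver and pathogenicity scores
#'
#' Aggregates per-variant driver (CHASM-like) and pathogenicity (VEST-like)
#' scores, both in \[0, 1\], to a gene-level ranking. For each gene the
#' combined score is the mean over its variants of (chasm + vest) / 2. A
#' gene-level p-value is obtained by Fisher-combining per-variant
#' pseudo-p-values defined as 1 - vest (a deterministic, monotone proxy for
#' pathogenicity evidence), then Benjamini-Hochberg adjusted across genes.
#' Genes are ranked by combined score, descending, ties broken
#' alphabetically.
#'
#' @param variants data.frame with columns gene, chasm, vest (typically the
#'   output of [filter_pass()])
#' @return object of class `gene_ranking`: data.frame with gene, n_variants,
#'   mean_chasm, mean_vest, combined_score, gene_p, gene_fdr, rank
#' @export
rank_genes <- function(variants) {
  need <- c("gene", "chasm", "vest")
  stopifnot(all(need %in% names(variants)))
  bad <- which(!is.finite(variants$chasm) | !is.finite(variants$vest))
  if (length(bad) > 0)
    stop("variant record(s) missing chasm/vest scores at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (any(variants$chasm < 0 | variants$chasm > 1 |
          variants$vest < 0 | variants$vest > 1))
    stop("chasm and vest scores must lie in [0, 1]")
  sp <- split(variants, variants$gene)
  rows <- lapply(sp, function(v) {
    data.frame(gene = v$gene[1], n_variants = nrow(v),
               mean_chasm = mean(v$chasm), mean_vest = mean(v$vest),
               combined_score = mean((v$chasm + v$vest) / 2),
               gene_p = fisher_combine(1 - v$vest),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$gene_fdr <- stats::p.adjust(out$gene_p, method = "BH")
  ord <- order(-out$combined_score, out$gene)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("gene_ranking", "data.frame"))
}

#' Genes exclusively significant in one group's ranking
#'
#' Restricts each ranking to genes with `gene_fdr` below the threshold, then
#' returns the responder-exclusive set (significant in responders but in
#' neither non-responders nor healthy controls) and the symmetric
#' non-responder-exclusive set.
#'
#' @param ranking_resp,ranking_nonresp,ranking_hc `gene_ranking` objects
#' @param fdr gene-level FDR threshold (strict)
#' @return list with `responder_exclusive`, `nonresponder_exclusive` and the
#'   per-group significant sets
#' @export
group_exclusive_genes <- function(ranking_resp, ranking_nonresp, ranking_hc,
                                  fdr = 0.05) {
  sig <- function(r) r$gene[r$gene_fdr < fdr]
  s_r <- sig(ranking_resp); s_n <- sig(ranking_nonresp); s_h <- sig(ranking_hc)
  list(responder_exclusive = setdiff(s_r, union(s_n, s_h)),
       nonresponder_exclusive = setdiff(s_n, union(s_r, s_h)),
       significant = list(responder = s_r, non_responder = s_n, hc = s_h))
}

#' Stratify patients by two mutation marker panels
#'
#' A patient is labeled "responder" with at least one PASS variant in a
#' responder-panel gene and none in the non-responder panel,
#' "non_responder" symmetrically, "unaltered" with PASS variants in neither
#' panel, and "mixed" with PASS variants in both (mixed patients are
#' reported but typically excluded from two-panel survival contrasts). Only
#' PASS variants count toward panel membership.
#'
#' @param variants cohort variant data.frame (patient, gene, filter, ...)
#' @param responder_panel,nonresponder_panel disjoint gene sets
#' @param patients optional full patient roster; patients without any
#'   variant record are labeled "unaltered"
#' @return data.frame with patient and subgroup
#' @export
stratify_cohort <- function(variants,
                            responder_panel = c("PTCH1", "DNMT3A", "PTPRS", "JAK2"),
                            nonresponder_panel = c("TNFAIP3", "BRCA1", "ASXL1", "GATA2"),
                            patients = NULL) {
  if (length(intersect(responder_panel, nonresponder_panel)) > 0)
    stop("panels must be disjoint")
  stopifnot(all(c("patient", "gene", "filter") %in% names(variants)))
  pass <- variants[variants$filter == "PASS", , drop = FALSE]
  if (is.null(patients)) patients <- sort(unique(variants$patient))
  in_r <- tapply(pass$gene %in% responder_panel, pass$patient, any)
  in_n <- tapply(pass$gene %in% nonresponder_panel, pass$patient, any)
  r <- stats::setNames(rep(FALSE, length(patients)), patients)
  n <- r
  r[names(in_r)] <- in_r
  n[names(in_n)] <- in_n
  subgroup <- ifelse(r & n, "mixed",
                     ifelse(r, "responder",
                            ifelse(n, "non_responder", "unaltered")))
  data.frame(patient = patients, subgroup = unname(subgroup[patients]),
             stringsAsFactors = FALSE)
}

#' Stratify patients by individual marker genes
#'
#' Single-gene stratification: a patient with PASS variants in exactly one
#' of the marker genes is labeled with that gene; patients hit in several
#' marker genes are labeled "multiple" and patients hit in none
#' "unaltered". With 8 marker genes this yields the 9-subgroup scheme
#' (8 single-gene groups + no-mutation) used for per-gene survival curves.
#'
#' @param variants cohort variant data.frame
#' @param genes marker genes to stratify on
#' @param patients optional full patient roster
#' @return data.frame with patient and subgroup (a gene name, "multiple" or
#'   "unaltered")
#' @export
stratify_by_gene <- function(variants, genes, patients = NULL) {
  stopifnot(all(c("patient", "gene", "filter") %in% names(variants)))
  pass <- variants[variants$filter == "PASS" & variants$gene %in% genes, ,
                   drop = FALSE]
  if (is.null(patients)) patients <- sort(unique(variants$patient))
  hits <- lapply(split(pass$gene, pass$patient), unique)
  subgroup <- vapply(patients, function(p) {
    h <- hits[[p]]
    if (is.null(h) || length(h) == 0) "unaltered"
    else if (length(h) == 1) h
    else "multiple"
  }, character(1))
  data.frame(patient = patients, subgroup = unname(subgroup),
             stringsAsFactors = FALSE)
}

#' Tumor mutational burden per subgroup with pairwise rank-sum tests
#'
#' TMB is the raw count of PASS variants per patient (no per-megabase
#' scaling; supply `denominator_mb` for per-Mb values). Reports the median
#' TMB per subgroup and two-sided Wilcoxon rank-sum p-values for all
#' subgroup pairs; subgroups without patients are omitted with a warning.
#'
#' @param variants cohort variant data.frame
#' @param labels data.frame with patient and subgroup (from
#'   [stratify_cohort()])
#' @param denominator_mb optional capture size in megabases for per-Mb TMB
#' @return list with `tmb` (patient, subgroup, tmb), `medians` (named
#'   vector) and `tests` (group_a, group_b, p)
#' @export
tmb_by_subgroup <- function(variants, labels, denominator_mb = NULL) {
  stopifnot(all(c("patient", "subgroup") %in% names(labels)))
  extra <- setdiff(unique(variants$patient), labels$patient)
  if (length(extra) > 0)
    stop("labels missing for patient(s): ",
         paste(utils::head(extra, 5), collapse = ", "))
  pass <- variants[variants$filter == "PASS", , drop = FALSE]
  counts <- table(factor(pass$patient, levels = labels$patient))
  tmb <- as.numeric(counts)
  if (!is.null(denominator_mb)) tmb <- tmb / denominator_mb
  tab <- data.frame(patient = labels$patient, subgroup = labels$subgroup,
                    tmb = tmb, stringsAsFactors = FALSE)
  present <- names(which(table(tab$subgroup) > 0))
  absent <- setdiff(unique(labels$subgroup), present)
  if (length(absent) > 0)
    warning("empty subgroup(s) omitted from tests: ",
            paste(absent, collapse = ", "))
  medians <- tapply(tab$tmb, tab$subgroup, stats::median)
  tests <- NULL
  if (length(present) >= 2) {
    pairs <- utils::combn(sort(present), 2)
    tests <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                        p = apply(pairs, 2, function(pr)
                          suppressWarnings(stats::wilcox.test(
                            tab$tmb[tab$subgroup == pr[1]],
                            tab$tmb[tab$subgroup == pr[2]])$p.value)),
                        stringsAsFactors = FALSE)
  }
  list(tmb = tab, medians = medians, tests = tests)
}
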