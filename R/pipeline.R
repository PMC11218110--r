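#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one object: the DEG
#' fold-change thresholds (2 for blood, 1.2 for cell lines), the FDR alpha,
#' the marker-filter correlation and p thresholds with the 10-20 panel-size
#' band, the gene-level FDR for mutation ranking, the default mutation
#' marker panels, and the synthetic-data settings for each stage.
#'
#' @param seed master integer seed; all stage seeds derive from it
#' @param fc_blood,fc_cell_line,alpha DEG thresholds
#' @param r_threshold,p_threshold,marker_min,marker_max marker-filter settings
#' @param gene_fdr gene-level FDR threshold for mutation ranking
#' @param responder_panel,nonresponder_panel mutation marker panels
#' @param deconv,cohort,surv named lists overriding stage defaults
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 1, fc_blood = 2, fc_cell_line = 1.2,
                            alpha = 0.05, r_threshold = 0.60,
                            p_threshold = 0.01, marker_min = 10,
                            marker_max = 20, gene_fdr = 0.05,
                            responder_panel = c("PTCH1", "DNMT3A", "PTPRS", "JAK2"),
                            nonresponder_panel = c("TNFAIP3", "BRCA1", "ASXL1", "GATA2"),
                            deconv = list(), cohort = list(), surv = list()) {
  stopifnot(fc_blood > 0, fc_cell_line > 0, alpha > 0, r_threshold > 0,
            p_threshold > 0, marker_min <= marker_max)
  deconv_def <- list(n_subsets = 10, markers_per_subset = 30,
                     n_mixtures = 50, noise_cv = 0.2,
                     contaminants_per_subset = 5)
  cohort_def <- list(n_hc = 5, n_resp = 12, n_nonresp = 17, n_genes = 2000,
                     n_planted_deg = 100, effect_log2fc = 2,
                     dispersion = 0.1)
  surv_def <- list(n_patients = 500,
                   hazard_ratios = c(responder = 0.5, non_responder = 1.4,
                                     unaltered = 1.0),
                   censor_rate = 0.2)
  structure(list(seed = as.integer(seed), fc_blood = fc_blood,
                 fc_cell_line = fc_cell_line, alpha = alpha,
                 r_threshold = r_threshold, p_threshold = p_threshold,
                 marker_min = marker_min, marker_max = marker_max,
                 gene_fdr = gene_fdr, responder_panel = responder_panel,
                 nonresponder_panel = nonresponder_panel,
                 deconv = utils::modifyList(deconv_def, deconv),
                 cohort = utils::modifyList(cohort_def, cohort),
                 surv = utils::modifyList(surv_def, surv)),
            class = "pipeline_config")
}

#' Run the full biomarker-discovery pipeline on synthetic data
#'
#' Chains every stage end-to-end with known ground truth: (1) signature
#' simulation, pseudo-bulk mixing, marker selection and abundance scoring,
#' with fraction-recovery diagnostics; (2) cohort simulation, normalization,
#' differential expression of responder and non-responder pre-treatment
#' blood vs healthy controls, Common/Unique set algebra, and
#' hierarchical-clustering stratification of pre-treatment samples on the
#' responder-unique DEGs; (3) variant/survival simulation, PASS filtering,
#' gene ranking, panel stratification, TMB comparison, Kaplan-Meier curves,
#' log-rank test and a Cox fit of the responder-panel subgroup against
#' unaltered patients. The run is fully deterministic given the config.
#'
#' @param config a [pipeline_config()]
#' @param out_json optional path; when given the report is written as JSON
#' @return nested report list (also written to `out_json` when requested)
#' @export
run_pipeline <- function(config = pipeline_config(), out_json = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  report <- list(config = unclass(config))

  ## -- deconvolution stage ------------------------------------------------
  dc <- config$deconv
  sig <- simulate_signatures(n_subsets = dc$n_subsets,
                             markers_per_subset = dc$markers_per_subset,
                             noise_cv = dc$noise_cv, seed = seed + 11)
  pb <- simulate_pseudobulk(sig, n_samples = dc$n_mixtures,
                            noise_cv = dc$noise_cv, seed = seed + 12)
  # contaminate candidate pools with background genes to make precision
  # a meaningful diagnostic
  bg <- grep("^BG_", colnames(sig$expression), value = TRUE)
  candidates <- lapply(seq_along(sig$marker_truth), function(i) {
    extra <- bg[((i - 1) * dc$contaminants_per_subset + 1):
                  (i * dc$contaminants_per_subset)]
    c(sig$marker_truth[[i]], extra)
  })
  names(candidates) <- names(sig$marker_truth)
  panel <- suppressWarnings(
    select_markers(pb$expr, candidates, r_threshold = config$r_threshold,
                   p_threshold = config$p_threshold,
                   min_k = config$marker_min, max_k = config$marker_max))
  kept <- retained_markers(panel)
  precision <- mean(unlist(lapply(names(kept), function(s)
    kept[[s]] %in% sig$marker_truth[[s]])))
  scores <- abundance_scores(pb$expr, panel)
  rho <- vapply(colnames(scores), function(s)
    stats::cor(pb$fractions[, s], scores[, s], method = "spearman"),
    numeric(1))
  report$deconvolution <- list(
    n_mixtures = dc$n_mixtures,
    marker_precision = precision,
    retained_per_subset = lengths(kept),
    spearman_by_subset = rho,
    spearman_min = min(rho))

  ## -- differential expression stage --------------------------------------
  ch <- config$cohort
  design <- cohort_design(n_hc = ch$n_hc, n_resp = ch$n_resp,
                          n_nonresp = ch$n_nonresp, n_genes = ch$n_genes,
                          n_planted_deg = ch$n_planted_deg,
                          effect_log2fc = ch$effect_log2fc,
                          dispersion = ch$dispersion, seed = seed + 21)
  sim <- simulate_cohort(design)
  norm <- normalize_counts(sim$expr)
  pre_or_hc <- is.na(sim$meta$timepoint) | sim$meta$timepoint == "pre"
  sub <- function(keep) list(expr = norm[, keep, drop = FALSE],
                             meta = sim$meta[keep, , drop = FALSE])
  rp <- sub(pre_or_hc & sim$meta$group %in% c("HC", "responder"))
  np <- sub(pre_or_hc & sim$meta$group %in% c("HC", "non_responder"))
  deg_resp <- de_test(rp$expr, rp$meta, c("HC", "responder"),
                      fc_threshold = config$fc_blood, alpha = config$alpha)
  deg_nonresp <- de_test(np$expr, np$meta, c("HC", "non_responder"),
                         fc_threshold = config$fc_blood, alpha = config$alpha)
  sets <- deg_set_algebra(list(responder = deg_resp,
                               non_responder = deg_nonresp))
  planted <- sim$truth$resp_pre_vs_hc
  sensitivity <- mean(planted %in% significant_genes(deg_resp))
  pre_cancer <- pre_or_hc & sim$meta$group %in% c("responder", "non_responder")
  strat <- stratify_by_degs(norm[, pre_cancer, drop = FALSE],
                            sets$unique$responder, k = 2,
                            true_labels = sim$meta$group[pre_cancer])
  report$diffexpr <- list(
    n_genes = ch$n_genes,
    deg_counts = list(responder_vs_hc = length(sets$sets$responder),
                      nonresponder_vs_hc = length(sets$sets$non_responder),
                      common = length(sets$common),
                      unique_responder = length(sets$unique$responder),
                      unique_nonresponder = length(sets$unique$non_responder)),
    planted_sensitivity = sensitivity,
    stratification = list(ari = strat$ari, purity = strat$purity))

  ## -- mutation + survival stage ------------------------------------------
  sv <- config$surv
  msim <- simulate_variants_and_survival(
    n_patients = sv$n_patients, responder_panel = config$responder_panel,
    nonresponder_panel = config$nonresponder_panel,
    hazard_ratios = sv$hazard_ratios, censor_rate = sv$censor_rate,
    seed = seed + 31)
  pass <- suppressMessages(filter_pass(msim$variants))
  ranking <- rank_genes(pass)
  panel_genes <- c(config$responder_panel, config$nonresponder_panel)
  top_k <- ranking$gene[seq_len(length(panel_genes))]
  labels <- stratify_cohort(pass, config$responder_panel,
                            config$nonresponder_panel,
                            patients = msim$survival$patient)
  accuracy <- mean(labels$subgroup == msim$truth[labels$patient])
  tmb <- suppressWarnings(tmb_by_subgroup(pass, labels))
  surv <- merge(msim$survival[, c("patient", "time_months", "event")],
                labels, by = "patient")
  keep2 <- surv$subgroup %in% c("responder", "unaltered")
  s2 <- surv[keep2, ]
  km <- km_by(s2$time_months, s2$event, s2$subgroup)
  lr <- logrank_test(s2$time_months, s2$event, s2$subgroup)
  cox <- cox_fit(s2$time_months, s2$event,
                 as.integer(s2$subgroup == "responder"))
  report$mutation_survival <- list(
    n_patients = sv$n_patients,
    panel_genes_in_top_ranks = mean(panel_genes %in% top_k),
    stratification_accuracy = accuracy,
    tmb_median = as.list(tmb$medians),
    km_median_months = lapply(km, function(x) x$median),
    logrank_p = lr$p,
    cox = list(hr = cox$hr, ci_lower = cox$ci_lower,
               ci_upper = cox$ci_upper, coef = cox$coef, se = cox$se),
    true_hr = unname(sv$hazard_ratios["responder"]))

  if (!is.null(out_json))
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  report
}
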