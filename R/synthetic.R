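#' Simulate immune cell-subset expression signatures with known markers
#'
#' Builds a subsets-by-genes matrix of mean expression (FPKM-like units) in
#' which each subset carries a disjoint block of marker genes enriched in
#' that subset relative to all others, plus a pool of background genes drawn
#' from a baseline shared across subsets. This emulates the structure of
#' marker-gene panels derived from peripheral blood single-cell profiles
#' (CD4/CD8 T cells, B cells, NK, NKT, dendritic cells, monocytes and
#' macrophage subsets) without requiring any external data.
#'
#' At least 30 candidate markers per subset are required, matching the
#' candidate-pool premise of correlation-based marker filtering: with fewer
#' candidates the downstream filter cannot produce a meaningful panel.
#'
#' @param n_subsets number of cell subsets (>= 2; default 10)
#' @param markers_per_subset candidate markers per subset (>= 30)
#' @param n_background_genes genes drawn from the shared baseline
#' @param enrichment factor by which a marker's mean expression in its home
#'   subset exceeds its mean in every other subset (default 8)
#' @param base_meanlog,base_sdlog log-normal parameters of baseline expression
#' @param noise_cv coefficient of variation of multiplicative noise, stored
#'   for downstream pseudo-bulk simulation
#' @param subset_names optional subset names; defaults to the ten blood
#'   subsets CD4, CD8, B, NK, NKT, DC, DC_ac, Macro, Macro_ac, Mon
#' @param seed integer seed
#' @return object of class `signature_set`: list with `expression`
#'   (subsets x genes), `marker_truth` (named list of marker gene IDs per
#'   subset, pairwise disjoint), `noise_cv`, `enrichment`
#' @export
simulate_signatures <- function(n_subsets = 10, markers_per_subset = 30,
                                n_background_genes = 200, enrichment = 8,
                                base_meanlog = log(20), base_sdlog = 0.5,
                                noise_cv = 0.2, subset_names = NULL,
                                seed = 1) {
  if (n_subsets < 2) stop("need at least 2 cell subsets")
  if (markers_per_subset < 30)
    stop("at least 30 candidate marker genes per subset are required; got ",
         markers_per_subset)
  if (enrichment <= 1) stop("enrichment factor must exceed 1")
  default_names <- c("CD4", "CD8", "B", "NK", "NKT", "DC", "DC_ac",
                     "Macro", "Macro_ac", "Mon")
  if (is.null(subset_names)) {
    subset_names <- if (n_subsets <= length(default_names))
      default_names[seq_len(n_subsets)]
    else paste0("subset", seq_len(n_subsets))
  }
  stopifnot(length(subset_names) == n_subsets)

  with_seed(seed, {
    marker_truth <- stats::setNames(vector("list", n_subsets), subset_names)
    gene_ids <- character(0)
    cols <- list()
    for (s in seq_len(n_subsets)) {
      ids <- sprintf("MK_%s_%02d", subset_names[s], seq_len(markers_per_subset))
      marker_truth[[s]] <- ids
      gene_ids <- c(gene_ids, ids)
      base <- stats::rlnorm(markers_per_subset, base_meanlog, base_sdlog)
      # off-target expression strictly below base; home subset = base * enrichment
      block <- matrix(NA_real_, nrow = n_subsets, ncol = markers_per_subset)
      for (g in seq_len(markers_per_subset)) {
        off <- base[g] * stats::runif(n_subsets - 1, 0.3, 1.0)
        block[-s, g] <- off
        block[s, g] <- base[g] * enrichment
      }
      cols[[s]] <- block
    }
    bg_ids <- sprintf("BG_%04d", seq_len(n_background_genes))
    bg_base <- stats::rlnorm(n_background_genes, base_meanlog, base_sdlog)
    bg_block <- matrix(rep(bg_base, each = n_subsets), nrow = n_subsets)
    expr <- do.call(cbind, c(cols, list(bg_block)))
    dimnames(expr) <- list(subset_names, c(gene_ids, bg_ids))

    structure(list(expression = expr, marker_truth = marker_truth,
                   noise_cv = noise_cv, enrichment = enrichment),
              class = "signature_set")
  })
}

#' Simulate pseudo-bulk mixtures from a signature set
#'
#' Each pseudo-bulk sample is a fraction-weighted sum of the subset
#' signatures, optionally multiplied by log-normal noise per gene and
#' sample. Mixing fractions are drawn from a symmetric Dirichlet (via
#' normalized gammas) unless supplied, and are returned as ground truth for
#' deconvolution recovery tests.
#'
#' @param sig a `signature_set` from [simulate_signatures()]
#' @param n_samples number of mixtures (>= 1)
#' @param alpha Dirichlet concentration, scalar or per-subset vector (> 0)
#' @param noise_cv coefficient of variation of the multiplicative noise;
#'   defaults to the value stored in `sig`; 0 disables noise exactly
#' @param fractions optional samples x subsets matrix of fixed fractions
#'   (rows must sum to 1); overrides Dirichlet sampling
#' @param seed integer seed
#' @return list with `expr` (genes x samples FPKM matrix) and `fractions`
#'   (samples x subsets, rows summing to 1)
#' @export
simulate_pseudobulk <- function(sig, n_samples = 50, alpha = 1,
                                noise_cv = sig$noise_cv, fractions = NULL,
                                seed = 1) {
  stopifnot(inherits(sig, "signature_set"), n_samples >= 1)
  n_sub <- nrow(sig$expression)
  if (is.null(fractions)) {
    if (any(alpha <= 0)) stop("Dirichlet concentration must be positive")
    alpha <- rep_len(alpha, n_sub)
  } else {
    fractions <- as.matrix(fractions)
    stopifnot(ncol(fractions) == n_sub, nrow(fractions) == n_samples)
    if (any(abs(rowSums(fractions) - 1) > 1e-9))
      stop("fraction rows must sum to 1")
  }

  with_seed(seed, {
    if (is.null(fractions)) {
      g <- matrix(stats::rgamma(n_samples * n_sub, shape = rep(alpha, each = n_samples)),
                  nrow = n_samples)
      fractions <- g / rowSums(g)
    }
    dimnames(fractions) <- list(sprintf("PB_%03d", seq_len(n_samples)),
                                rownames(sig$expression))
    bulk <- t(fractions %*% sig$expression)  # genes x samples
    if (noise_cv > 0) {
      sigma <- sqrt(log(1 + noise_cv^2))
      eps <- matrix(stats::rnorm(length(bulk), 0, sigma), nrow = nrow(bulk))
      bulk <- bulk * exp(eps)
    }
    colnames(bulk) <- rownames(fractions)
    list(expr = expression_matrix(bulk, "FPKM"), fractions = fractions)
  })
}

#' Construct a cohort simulation design
#'
#' Defaults mirror the discovery cohort of the neoadjuvant anti-PD-1 study
#' structure this pipeline targets: 5 healthy controls, 12 responders
#' (pathological complete response) and 17 non-responders, with paired
#' pre-/on-treatment blood samples for the cancer patients.
#'
#' @param n_hc,n_resp,n_nonresp group sizes (each >= 2)
#' @param paired simulate paired pre/on samples sharing a subject effect
#' @param n_genes total genes
#' @param n_planted_deg genes planted per contrast
#' @param effect_log2fc planted log2 fold change (> 0)
#' @param dispersion negative-binomial dispersion scale (gene-wise values are
#'   drawn log-normally around it)
#' @param deg_direction "both" plants half the DEGs up and half down within
#'   each contrast (the usual volcano-plot structure); "up" plants all up
#' @param censor_rate expected fraction of censored survival times in \[0, 1)
#' @param hazard_ratios named vector of true hazard ratios per mutation
#'   subgroup
#' @param seed integer seed
#' @return list of class `cohort_design`
#' @export
cohort_design <- function(n_hc = 5, n_resp = 12, n_nonresp = 17, paired = TRUE,
                          n_genes = 2000, n_planted_deg = 100,
                          effect_log2fc = 2, dispersion = 0.1,
                          deg_direction = c("both", "up"),
                          censor_rate = 0.2,
                          hazard_ratios = c(responder = 0.5,
                                            non_responder = 1.4,
                                            unaltered = 1.0),
                          seed = 1) {
  deg_direction <- match.arg(deg_direction)
  stopifnot(n_hc >= 2, n_resp >= 2, n_nonresp >= 2)
  if (n_planted_deg > 0 && effect_log2fc <= 0)
    stop("effect_log2fc must be positive")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0, 1)")
  if (4 * n_planted_deg > n_genes)
    stop("not enough genes to plant ", n_planted_deg, " DEGs in 4 contrasts")
  structure(list(n_hc = n_hc, n_resp = n_resp, n_nonresp = n_nonresp,
                 paired = paired, n_genes = n_genes,
                 n_planted_deg = n_planted_deg, effect_log2fc = effect_log2fc,
                 dispersion = dispersion, deg_direction = deg_direction,
                 censor_rate = censor_rate,
                 hazard_ratios = hazard_ratios, seed = seed),
            class = "cohort_design")
}

#' Simulate a three-group cohort expression matrix with planted DEGs
#'
#' Counts follow a negative-binomial model with gene-wise dispersion drawn
#' log-normally. Disjoint blocks of genes receive an `effect_log2fc` shift in
#' four contrasts: on- vs pre-treatment within responders and within
#' non-responders, and responder / non-responder (both timepoints) vs healthy
#' controls. With `deg_direction = "both"` (the default) half of each block
#' is shifted up and half down. Paired samples share a per-subject
#' log-normal random effect.
#'
#' @param design a `cohort_design`
#' @return list with `expr` (genes x samples raw counts), `meta`
#'   (sample, group, timepoint, pair_id, batch), `truth` (named list of
#'   planted gene IDs per contrast) and `truth_sign` (per contrast, the
#'   signed direction of each planted gene, named by gene)
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  d <- design
  hc_ids <- sprintf("HC_%02d", seq_len(d$n_hc))
  resp_ids <- sprintf("R%02d", seq_len(d$n_resp))
  nonresp_ids <- sprintf("N%02d", seq_len(d$n_nonresp))

  meta <- rbind(
    data.frame(sample = hc_ids, group = "HC", timepoint = NA_character_,
               pair_id = NA_character_, stringsAsFactors = FALSE),
    data.frame(sample = c(paste0(resp_ids, "_pre"), paste0(resp_ids, "_on")),
               group = "responder",
               timepoint = rep(c("pre", "on"), each = d$n_resp),
               pair_id = rep(resp_ids, 2), stringsAsFactors = FALSE),
    data.frame(sample = c(paste0(nonresp_ids, "_pre"), paste0(nonresp_ids, "_on")),
               group = "non_responder",
               timepoint = rep(c("pre", "on"), each = d$n_nonresp),
               pair_id = rep(nonresp_ids, 2), stringsAsFactors = FALSE)
  )
  meta$batch <- "b1"
  n_samp <- nrow(meta)
  genes <- sprintf("G%05d", seq_len(d$n_genes))

  k <- d$n_planted_deg
  truth <- list(resp_on_vs_pre = genes[seq_len(k)],
                nonresp_on_vs_pre = genes[k + seq_len(k)],
                resp_pre_vs_hc = genes[2 * k + seq_len(k)],
                nonresp_pre_vs_hc = genes[3 * k + seq_len(k)])
  if (k == 0) truth <- lapply(truth, function(x) character(0))
  dir_block <- if (d$deg_direction == "both")
    rep(c(1, -1), length.out = k) else rep(1, k)
  truth_sign <- lapply(truth, function(g) stats::setNames(dir_block[seq_along(g)], g))

  with_seed(d$seed, {
    mu <- stats::rlnorm(d$n_genes, log(100), 1)
    phi <- stats::rlnorm(d$n_genes, log(d$dispersion), 0.3)

    # per-gene, per-sample log2 effect offsets
    shift <- matrix(0, nrow = d$n_genes, ncol = n_samp,
                    dimnames = list(genes, meta$sample))
    is_on <- !is.na(meta$timepoint) & meta$timepoint == "on"
    resp <- meta$group == "responder"
    nonresp <- meta$group == "non_responder"
    e <- d$effect_log2fc
    add_effect <- function(contrast, cols) {
      g <- truth[[contrast]]
      if (length(g) > 0)
        shift[g, cols] <<- shift[g, cols] + e * truth_sign[[contrast]]
    }
    add_effect("resp_on_vs_pre", resp & is_on)
    add_effect("nonresp_on_vs_pre", nonresp & is_on)
    add_effect("resp_pre_vs_hc", resp)
    add_effect("nonresp_pre_vs_hc", nonresp)

    subj_eff <- stats::setNames(rep(0, n_samp), meta$sample)
    if (d$paired) {
      subjects <- unique(stats::na.omit(meta$pair_id))
      u <- stats::setNames(stats::rnorm(length(subjects), 0, 0.1), subjects)
      has_pair <- !is.na(meta$pair_id)
      subj_eff[has_pair] <- u[meta$pair_id[has_pair]]
    }

    mu_mat <- outer(mu, exp(subj_eff)) * 2^shift
    counts <- matrix(stats::rnbinom(length(mu_mat), mu = mu_mat,
                                    size = rep(1 / phi, n_samp)),
                     nrow = d$n_genes, dimnames = dimnames(shift))
    list(expr = expression_matrix(counts, "counts"), meta = meta,
         truth = truth, truth_sign = truth_sign, design = d)
  })
}

#' Simulate a mutation-stratified cohort with variants and survival
#'
#' Each patient is assigned to one of three subgroups (responder-panel
#' mutated, non-responder-panel mutated, unaltered). Panel patients receive
#' at least one PASS variant in a gene of their panel; all patients receive
#' background PASS variants in non-panel genes plus occasional non-PASS
#' calls. Panel variants carry high driver (CHASM-like) and pathogenicity
#' (VEST-like) scores near 1; background variants carry low scores. Overall
#' survival times are exponential with subgroup-specific hazard ratios and
#' independent exponential censoring calibrated to `censor_rate`.
#'
#' @param n_patients cohort size
#' @param responder_panel,nonresponder_panel disjoint marker gene sets
#' @param subgroup_probs named probabilities for responder / non_responder /
#'   unaltered assignment (sums to 1)
#' @param background_genes pool of non-panel gene symbols
#' @param background_rate mean background PASS variants per patient
#' @param nonpass_rate mean non-PASS (filtered-out) calls per patient
#' @param hazard_ratios named true hazard ratios per subgroup
#' @param baseline_hazard events per month for the unaltered subgroup
#'   (default log(2)/17, i.e. 17-month median survival)
#' @param censor_rate expected censored fraction in \[0, 1)
#' @param seed integer seed
#' @return list with `variants` (patient, gene, chrom, pos, ref, alt, filter,
#'   chasm, vest, class), `survival` (patient, time_months, event, subgroup,
#'   tmb) and `truth` (assigned subgroup per patient)
#' @export
simulate_variants_and_survival <- function(
    n_patients = 200,
    responder_panel = c("PTCH1", "DNMT3A", "PTPRS", "JAK2"),
    nonresponder_panel = c("TNFAIP3", "BRCA1", "ASXL1", "GATA2"),
    subgroup_probs = c(responder = 0.10, non_responder = 0.15, unaltered = 0.75),
    background_genes = sprintf("BGENE%02d", 1:40),
    background_rate = 3, nonpass_rate = 0.5,
    hazard_ratios = c(responder = 0.5, non_responder = 1.4, unaltered = 1.0),
    baseline_hazard = log(2) / 17, censor_rate = 0.2, seed = 1) {
  if (length(intersect(responder_panel, nonresponder_panel)) > 0)
    stop("responder and non-responder panels must be disjoint")
  if (length(intersect(background_genes, c(responder_panel, nonresponder_panel))) > 0)
    stop("background gene pool must not contain panel genes")
  stopifnot(abs(sum(subgroup_probs) - 1) < 1e-9)
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0, 1)")
  required <- c("responder", "non_responder", "unaltered")
  stopifnot(all(required %in% names(subgroup_probs)),
            all(required %in% names(hazard_ratios)))

  all_genes <- c(responder_panel, nonresponder_panel, background_genes)
  gene_chrom <- stats::setNames(paste0("chr", (seq_along(all_genes) %% 22) + 1),
                                all_genes)
  gene_base <- stats::setNames(1e6 * seq_along(all_genes), all_genes)
  bases <- c("A", "C", "G", "T")

  with_seed(seed, {
    patients <- sprintf("P%04d", seq_len(n_patients))
    subgroup <- sample(required, n_patients, replace = TRUE,
                       prob = subgroup_probs[required])

    rec <- list()
    mk_records <- function(patient, genes, filter, hi_score) {
      n <- length(genes)
      if (n == 0) return(NULL)
      sc <- function() if (hi_score) stats::runif(n, 0.85, 0.99) else stats::runif(n, 0.05, 0.60)
      data.frame(patient = patient, gene = genes,
                 chrom = gene_chrom[genes],
                 pos = gene_base[genes] + sample.int(5e5, n, replace = TRUE),
                 ref = sample(bases, n, replace = TRUE),
                 alt = sample(bases, n, replace = TRUE),
                 filter = filter, chasm = sc(), vest = sc(),
                 class = "missense", stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_patients)) {
      panel <- switch(subgroup[i],
                      responder = responder_panel,
                      non_responder = nonresponder_panel,
                      unaltered = character(0))
      p_rec <- NULL
      if (length(panel) > 0) {
        n_hit <- 1 + stats::rpois(1, 0.5)
        hit <- sample(panel, min(n_hit, length(panel)))
        p_rec <- mk_records(patients[i], hit, "PASS", hi_score = TRUE)
      }
      n_bg <- stats::rpois(1, background_rate)
      bg_rec <- mk_records(patients[i],
                           sample(background_genes, n_bg, replace = TRUE),
                           "PASS", hi_score = FALSE)
      n_lq <- stats::rpois(1, nonpass_rate)
      lq_rec <- mk_records(patients[i],
                           sample(all_genes, n_lq, replace = TRUE),
                           "LowQual", hi_score = FALSE)
      rec[[i]] <- rbind(p_rec, bg_rec, lq_rec)
    }
    variants <- do.call(rbind, rec)
    rownames(variants) <- NULL

    hr <- hazard_ratios[subgroup]
    rate <- baseline_hazard * hr
    t_event <- stats::rexp(n_patients, rate)
    if (censor_rate > 0) {
      c_rate <- rate * censor_rate / (1 - censor_rate)
      t_cens <- stats::rexp(n_patients, c_rate)
    } else {
      t_cens <- rep(Inf, n_patients)
    }
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    pass <- variants[variants$filter == "PASS", ]
    tmb <- stats::setNames(rep(0L, n_patients), patients)
    tb <- table(pass$patient)
    tmb[names(tb)] <- as.integer(tb)

    surv <- data.frame(patient = patients, time_months = time, event = event,
                       subgroup = subgroup, tmb = as.integer(tmb),
                       stringsAsFactors = FALSE)
    list(variants = variants, survival = surv,
         truth = stats::setNames(subgroup, patients))
  })
}
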