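test_that("perfectly correlated candidates are all retained with avg_r = 1", {
  base <- c(1, 2, 4, 8, 16, 32)
  genes <- paste0("g", 1:5)
  # exact scalar multiples on the log-free scale are not perfectly
  # correlated after log2(x+1); build perfect correlation on the log scale
  expr <- toy_expr(unlist(lapply(1:5, function(k) 2^(k * log2(base + 1)) - 1)),
                   genes, paste0("s", 1:6))
  panel <- suppressWarnings(
    select_markers(expr, list(sub1 = genes), min_k = 2, max_k = 20))
  expect_true(all(panel$retained))
  expect_equal(panel$avg_r, rep(1, 5), tolerance = 1e-12)
})

test_that("avg_r matches a brute-force pairwise Pearson oracle on a toy matrix", {
  set.seed(42)
  genes <- paste0("g", 1:4)
  expr <- toy_expr(abs(rnorm(24, 50, 20)), genes, paste0("s", 1:6))
  panel <- suppressWarnings(select_markers(expr, list(sub1 = genes),
                                           r_threshold = -2, p_threshold = 2))
  L <- log2(expr + 1)
  for (i in seq_along(genes)) {
    rs <- vapply(setdiff(seq_along(genes), i),
                 function(j) cor(L[i, ], L[j, ]), numeric(1))
    expect_equal(panel$avg_r[panel$gene == genes[i]], mean(rs),
                 tolerance = 1e-12)
    ps <- vapply(setdiff(seq_along(genes), i),
                 function(j) cor.test(L[i, ], L[j, ])$p.value, numeric(1))
    expect_equal(panel$combined_p[panel$gene == genes[i]],
                 pchisq(-2 * sum(log(ps)), df = 2 * length(ps),
                        lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("marker filter thresholds are strict inequalities", {
  # build two genes whose log2 profiles correlate exactly 0.59
  n <- 20
  x <- scale(rnorm_fixed(n, seed = 1))[, 1]
  z <- residuals(lm(rnorm_fixed(n, seed = 2) ~ x))
  z <- scale(z)[, 1]
  y <- 0.59 * x + sqrt(1 - 0.59^2) * z
  expr <- rbind(gA = 2^(5 + x) - 1, gB = 2^(5 + y) - 1)
  colnames(expr) <- paste0("s", 1:n)
  expect_equal(cor(log2(expr["gA", ] + 1), log2(expr["gB", ] + 1)), 0.59,
               tolerance = 1e-12)
  panel <- suppressWarnings(
    select_markers(expr, list(sub1 = c("gA", "gB")), r_threshold = 0.60))
  expect_false(any(panel$retained))  # avg_r = 0.59 < 0.60: excluded
  # identical profiles (r = 1) are retained at threshold 0.60 ...
  expr2 <- rbind(gA = expr["gA", ], gB = expr["gA", ])
  panel2 <- suppressWarnings(
    select_markers(expr2, list(sub1 = c("gA", "gB")), r_threshold = 0.60))
  expect_true(all(panel2$retained))
  # ... but excluded when the threshold equals avg_r exactly (strict >)
  panel3 <- suppressWarnings(
    select_markers(expr2, list(sub1 = c("gA", "gB")), r_threshold = 1.0))
  expect_false(any(panel3$retained))
})

test_that("select_markers caps panels at max_k with alphabetical tie-breaks and is order-invariant", {
  sig <- simulate_signatures(n_subsets = 2, markers_per_subset = 30, seed = 4)
  pb <- simulate_pseudobulk(sig, n_samples = 30, noise_cv = 0.1, seed = 4)
  panel <- select_markers(pb$expr, sig$marker_truth)
  kept <- retained_markers(panel)
  expect_true(all(lengths(kept) <= 20))
  # permuting candidate order leaves the retained set unchanged
  shuffled <- lapply(sig$marker_truth, function(g) g[c(17:30, 1:16)])
  panel2 <- select_markers(pb$expr, shuffled)
  expect_identical(lapply(retained_markers(panel2), sort),
                   lapply(kept, sort))
  # missing gene and too-few-samples errors
  expect_error(select_markers(pb$expr[, 1:2], sig$marker_truth), "3 samples")
  expect_error(select_markers(pb$expr, list(s1 = c("NOPE", "MK_CD4_01"))),
               "NOPE")
})

test_that("abundance scores are the mean log2 expression of retained markers", {
  genes <- c("m1", "m2", "m3")
  # FPKM {1,3,7} with pseudocount 1 -> mean(1,2,3) = 2 exactly
  expr <- toy_expr(c(1, 1, 3, 3, 7, 7), genes, c("sA", "sB"))
  panel <- structure(
    data.frame(subset = "T", gene = genes, avg_r = 1, combined_p = 0,
               retained = TRUE, stringsAsFactors = FALSE),
    class = c("marker_panel", "data.frame"))
  sc <- abundance_scores(expr, panel)
  expect_equal(unname(sc[, "T"]), c(2, 2))
  # all-zero FPKM scores 0
  expr0 <- toy_expr(rep(0, 6), genes, c("sA", "sB"))
  expect_equal(unname(abundance_scores(expr0, panel)[, "T"]), c(0, 0))
  # spreadsheet-style recomputation on a 3-subset, 10-sample matrix
  sig <- simulate_signatures(n_subsets = 3, markers_per_subset = 30, seed = 8)
  pb <- simulate_pseudobulk(sig, n_samples = 10, seed = 8)
  p3 <- select_markers(pb$expr, sig$marker_truth)
  sc3 <- abundance_scores(pb$expr, p3)
  kept <- retained_markers(p3)
  for (s in names(kept)) for (j in 1:10) {
    manual <- mean(log2(pb$expr[kept[[s]], j] + 1))
    expect_equal(unname(sc3[j, s]), manual, tolerance = 1e-12)
  }
  # empty retained set errors
  panel$retained <- FALSE
  expect_error(abundance_scores(expr, panel), "no retained markers")
})

test_that("score table permutes with sample order", {
  sig <- simulate_signatures(n_subsets = 2, markers_per_subset = 30, seed = 6)
  pb <- simulate_pseudobulk(sig, n_samples = 8, seed = 6)
  panel <- select_markers(pb$expr, sig$marker_truth)
  sc <- abundance_scores(pb$expr, panel)
  perm <- c(5, 3, 8, 1, 2, 7, 6, 4)
  sc_p <- abundance_scores(pb$expr[, perm], panel)
  expect_equal(unname(sc_p), unname(sc[perm, ]), ignore_attr = TRUE)
})

test_that("group comparisons reproduce the closed-form t statistics", {
  set.seed(7)
  scores <- matrix(rnorm(40), ncol = 2,
                   dimnames = list(paste0("s", 1:20), c("CD4", "CD8")))
  meta <- toy_meta(paste0("s", 1:20), rep(c("pre", "on"), each = 10))
  res <- compare_scores(scores, meta, c("pre", "on"))
  for (k in 1:2) {
    a <- scores[1:10, k]; b <- scores[11:20, k]
    tt <- (mean(b) - mean(a)) / sqrt(var(a) / 10 + var(b) / 10)
    expect_equal(res$t[k], tt, tolerance = 1e-10)
    df <- (var(a) / 10 + var(b) / 10)^2 /
      ((var(a) / 10)^2 / 9 + (var(b) / 10)^2 / 9)
    expect_equal(res$p[k], 2 * pt(-abs(tt), df), tolerance = 1e-10)
  }
  # identical groups -> t = 0, p = 1
  sc2 <- rbind(scores[1:10, ], scores[1:10, ])
  rownames(sc2) <- paste0("s", 1:20)
  res2 <- compare_scores(sc2, meta, c("pre", "on"))
  expect_equal(res2$t, c(0, 0), tolerance = 1e-12)
  expect_equal(res2$p, c(1, 1), tolerance = 1e-12)
})

test_that("paired comparisons use within-pair differences and a sign-test fallback", {
  scores <- matrix(c(1, 2, 3, 4, 2, 3, 4, 5), ncol = 1,
                   dimnames = list(paste0("s", 1:8), "CD4"))
  meta <- data.frame(sample = paste0("s", 1:8),
                     group = rep(c("pre", "on"), each = 4),
                     pair_id = rep(paste0("p", 1:4), 2),
                     stringsAsFactors = FALSE)
  # constant differences {1,1,1,1}: documented sign-test fallback
  expect_warning(res <- compare_scores(scores, meta, c("pre", "on"),
                                       paired = TRUE),
                 "zero-variance")
  expect_equal(res$mean_diff, 1)
  expect_equal(res$method, "sign")
  expect_equal(res$p, binom.test(4, 4)$p.value)
  # orphan pairs are reported
  meta$pair_id[8] <- "p9"
  expect_error(compare_scores(scores, meta, c("pre", "on"), paired = TRUE),
               "p9")
})

test_that("abundance scores recover mixing fractions monotonically", {
  sig <- simulate_signatures(n_subsets = 4, markers_per_subset = 30,
                             noise_cv = 0.2, seed = 10)
  pb <- simulate_pseudobulk(sig, n_samples = 50, noise_cv = 0.2, seed = 10)
  panel <- select_markers(pb$expr, sig$marker_truth)
  sc <- abundance_scores(pb$expr, panel)
  for (s in colnames(sc)) {
    rho <- cor(pb$fractions[, s], sc[, s], method = "spearman")
    expect_gte(rho, 0.8)
  }
})
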