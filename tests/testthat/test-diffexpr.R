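test_that("median-of-ratios size factors behave on identity, scaling and a brute-force oracle", {
  set.seed(3)
  a <- rpois(50, 100) + 1
  m <- cbind(s1 = a, s2 = a)
  rownames(m) <- paste0("g", 1:50)
  norm <- normalize_counts(m)
  expect_equal(unname(attr(norm, "size_factors")), c(1, 1))

  m2 <- cbind(s1 = a, s2 = 2 * a)
  rownames(m2) <- paste0("g", 1:50)
  sf <- attr(normalize_counts(m2), "size_factors")
  expect_equal(unname(sf["s2"] / sf["s1"]), 2, tolerance = 1e-12)

  # independent brute-force median-of-ratios on a random 50-gene matrix
  m3 <- matrix(rpois(150, 80) + 1, nrow = 50,
               dimnames = list(paste0("g", 1:50), paste0("s", 1:3)))
  sf3 <- attr(normalize_counts(m3), "size_factors")
  geo <- exp(rowMeans(log(m3)))
  raw <- vapply(1:3, function(j) median(m3[, j] / geo), numeric(1))
  expect_equal(unname(sf3), raw / exp(mean(log(raw))), tolerance = 1e-12)

  # idempotence: renormalizing gives unit factors
  sf_again <- attr(normalize_counts(normalize_counts(m3)), "size_factors")
  expect_equal(unname(sf_again), c(1, 1, 1), tolerance = 1e-9)

  expect_error(normalize_counts(matrix(0, 2, 2,
    dimnames = list(c("a", "b"), c("x", "y")))), "all-zero")
})

test_that("de_test matches per-gene t.test results and applies both threshold conditions", {
  set.seed(21)
  n <- 8
  expr <- matrix(rlnorm(40 * 2 * n, log(50), 0.6), nrow = 40,
                 dimnames = list(sprintf("g%02d", 1:40),
                                 paste0("s", 1:(2 * n))))
  meta <- toy_meta(colnames(expr), rep(c("A", "B"), each = n))
  tab <- de_test(expr, meta, c("A", "B"))
  L <- log2(expr + 1)
  for (g in c(1, 7, 23, 40)) {
    tt <- t.test(L[g, (n + 1):(2 * n)], L[g, 1:n])
    expect_equal(tab$t[g], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(tab$p_raw[g], tt$p.value, tolerance = 1e-10)
  }
  expect_equal(tab$p_fdr, p.adjust(tab$p_raw, "BH"))

  # fold change 1.9 with tiny p is NOT significant at threshold 2
  expr2 <- expr
  expr2["g01", meta$group == "B"] <- expr2["g01", meta$group == "A"] * 1.9
  tab2 <- de_test(expr2, meta, c("A", "B"))
  expect_equal(tab2$fold_change[1], 1.9, tolerance = 1e-9)
  expect_false(tab2$significant[1])
  # and a clearly shifted gene is significant
  expr2["g02", meta$group == "B"] <- expr2["g02", meta$group == "A"] * 8
  tab3 <- de_test(expr2, meta, c("A", "B"))
  expect_true(tab3$significant[2])

  # constant gene: p = 1, flagged, not dropped
  expr2["g03", ] <- 5
  tab4 <- de_test(expr2, meta, c("A", "B"))
  expect_true(tab4$constant[3])
  expect_equal(tab4$p_raw[3], 1)
  expect_equal(nrow(tab4), 40)
})

test_that("swapping contrast groups negates log2fc exactly", {
  set.seed(5)
  expr <- matrix(rlnorm(200, log(30), 1), nrow = 20,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  meta <- toy_meta(colnames(expr), rep(c("A", "B"), each = 5))
  ab <- de_test(expr, meta, c("A", "B"))
  ba <- de_test(expr, meta, c("B", "A"))
  expect_equal(ba$log2fc, -ab$log2fc, tolerance = 1e-12)
  expect_equal(ba$p_raw, ab$p_raw, tolerance = 1e-12)
})

test_that("paired de_test uses within-pair differences", {
  d <- cohort_design(n_resp = 10, n_nonresp = 2, n_hc = 2, n_genes = 100,
                     n_planted_deg = 10, seed = 31)
  sim <- simulate_cohort(d)
  keep <- sim$meta$group == "responder"
  tab <- de_test(sim$expr[, keep], sim$meta[keep, ], c("pre", "on"),
                 group_col = "timepoint", paired = TRUE)
  L <- log2(sim$expr[, keep] + 1)
  meta <- sim$meta[keep, ]
  # recompute gene 1 with an explicit paired t.test
  pre_cols <- meta$sample[meta$timepoint == "pre"]
  on_cols <- meta$sample[meta$timepoint == "on"]
  o <- order(meta$pair_id[match(pre_cols, meta$sample)])
  o2 <- order(meta$pair_id[match(on_cols, meta$sample)])
  dvec <- L["G00001", on_cols[o2]] - L["G00001", pre_cols[o]]
  tt <- t.test(dvec)
  expect_equal(tab$t[1], unname(tt$statistic), tolerance = 1e-10)
  expect_equal(tab$p_raw[1], tt$p.value, tolerance = 1e-10)
})

test_that("DEG set algebra equals brute-force enumeration", {
  # identity: two identical tables
  s <- c("g1", "g2", "g3")
  res <- deg_set_algebra(list(A = s, B = s))
  expect_equal(sort(res$common), sort(s))
  expect_true(all(lengths(res$unique) == 0))

  # enumerable two-set case
  res2 <- deg_set_algebra(list(A = c("g1", "g2", "g3"), B = "g2"))
  expect_equal(res2$common, "g2")
  expect_equal(sort(res2$unique$A), c("g1", "g3"))
  expect_length(res2$unique$B, 0)

  # three-set case against exhaustive membership enumeration
  universe <- paste0("g", 1:30)
  sets <- list(A = sample(universe, 12), B = sample(universe, 15),
               C = sample(universe, 9))
  res3 <- deg_set_algebra(sets)
  for (g in universe) {
    inA <- g %in% sets$A; inB <- g %in% sets$B; inC <- g %in% sets$C
    expect_equal(g %in% res3$common, inA && inB && inC)
    expect_equal(g %in% res3$unique$A, inA && !inB && !inC)
    expect_equal(g %in% res3$unique$B, !inA && inB && !inC)
    expect_equal(g %in% res3$unique$C, !inA && !inB && inC)
  }
  # conservation and disjointness
  expect_lte(length(res3$common) + sum(lengths(res3$unique)),
             sum(lengths(sets)))
  expect_length(intersect(res3$unique$A, res3$unique$B), 0)
})

test_that("hierarchical stratification separates planted clusters and not random labels", {
  # two well-separated mean vectors -> ARI 1
  set.seed(13)
  mu1 <- rlnorm(40, log(50), 0.5)
  mu2 <- mu1 * rep(c(4, 0.25), 20)
  expr <- cbind(
    matrix(rlnorm(40 * 8, log(mu1), 0.2), nrow = 40),
    matrix(rlnorm(40 * 8, log(mu2), 0.2), nrow = 40))
  dimnames(expr) <- list(paste0("g", 1:40), paste0("s", 1:16))
  truth <- rep(c("x", "y"), each = 8)
  st <- stratify_by_degs(expr, rownames(expr), k = 2, true_labels = truth)
  expect_equal(st$ari, 1)
  expect_equal(st$purity, 1)

  # random labels vs clusters: ARI concentrates near 0
  aris <- vapply(1:50, function(i) {
    perm <- withr::with_seed(100 + i, sample(truth))
    adjusted_rand_index(st$labels, perm)
  }, numeric(1))
  expect_lt(mean(abs(aris)), 0.15)

  expect_error(stratify_by_degs(expr, "g1"), "at least 2")
  expect_error(stratify_by_degs(expr, c("g1", "nope")), "nope")
})

test_that("ARI and purity agree with the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(77)
  for (i in 1:20) {
    a <- sample(1:3, 40, replace = TRUE)
    b <- sample(1:4, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("2^-ddCt closed forms", {
  expect_equal(ddct(20, 20, 20, 20), 1)
  expect_equal(ddct(19, 20, 20, 20), 2)   # ddCt = -1
  expect_equal(ddct(25, 20, 24, 20), 0.5) # ddCt = 1
  expect_error(ddct(NA, 20, 20, 20))
})

test_that("BH adjustment is monotone and bounded", {
  set.seed(9)
  expr <- matrix(rlnorm(500 * 12, log(40), 0.7), nrow = 500,
                 dimnames = list(paste0("g", 1:500), paste0("s", 1:12)))
  meta <- toy_meta(colnames(expr), rep(c("A", "B"), each = 6))
  tab <- de_test(expr, meta, c("A", "B"))
  expect_true(all(tab$p_fdr >= tab$p_raw - 1e-15))
  expect_true(all(tab$p_fdr <= 1))
  ord <- order(tab$p_raw)
  expect_true(all(diff(tab$p_fdr[ord]) >= -1e-15))
})
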