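make_matrix <- function(vals, kind = "lfq_intensity") {
  expression_matrix(vals, kind)
}

test_that("pairwise correlations match definitions and the rank oracle", {
  m <- matrix(c(1, 2, 3, 6, 5, 4, 1, 2, 3), 3,
              dimnames = list(c("f1", "f2", "f3"), c("a", "b", "c")))
  pr <- pairwise_correlations(make_matrix(m), method = "both")
  # duplicated column -> r = 1 for both methods
  ac <- pr[pr$sample_a == "a" & pr$sample_b == "c", ]
  expect_equal(ac$r, c(1, 1))
  # anti-monotone columns -> Spearman -1
  ab <- pr[pr$sample_a == "a" & pr$sample_b == "b" & pr$method == "spearman", ]
  expect_equal(ab$r, -1)

  set.seed(13)
  rm <- matrix(exp(rnorm(40, 10, 1)), 10, 4,
               dimnames = list(sprintf("f%d", 1:10), sprintf("s%d", 1:4)))
  pr2 <- pairwise_correlations(make_matrix(rm), method = "spearman")
  for (i in seq_len(nrow(pr2))) {
    expect_equal(pr2$r[i],
                 oracle_spearman(rm[, pr2$sample_a[i]], rm[, pr2$sample_b[i]]),
                 tolerance = 1e-12)
  }
})

test_that("spearman correlations are invariant under strictly monotone transforms", {
  set.seed(21)
  rm <- matrix(exp(rnorm(60, 8, 1)), 20, 3,
               dimnames = list(sprintf("f%d", 1:20), c("s1", "s2", "s3")))
  a <- pairwise_correlations(make_matrix(rm), method = "spearman")
  b <- pairwise_correlations(make_matrix(rm^3 + 5), method = "spearman")
  expect_equal(a$r, b$r, tolerance = 1e-12)
})

test_that("pairs with too few usable features are rejected by name", {
  m <- matrix(c(1, NA, NA, 2, NA, NA), 3,
              dimnames = list(c("f1", "f2", "f3"), c("x", "y")))
  expect_error(pairwise_correlations(make_matrix(m), missing_policy = "pairwise"),
               "\\(x, y\\).*fewer than 3")
})

test_that("group assignment reproduces the cohort pair combinatorics", {
  ann <- cohort_annotation(3, 3, 3)
  pairs <- expand.grid(i = seq_len(27), j = seq_len(27))
  pairs <- pairs[pairs$i < pairs$j, ]
  cs <- data.frame(sample_a = ann$sample[pairs$i], sample_b = ann$sample[pairs$j],
                   method = "spearman", r = 0.5, stringsAsFactors = FALSE)
  class(cs) <- c("correlation_set", "data.frame")
  g <- assign_groups(cs, ann)
  counts <- table(g$group)
  expect_identical(nrow(g), 351L)                          # C(27,2)
  expect_identical(unname(counts[["G2_intra_patient"]]), 27L)   # 9 * C(3,2)
  expect_identical(unname(counts[["G1_intra_subtype"]]), 81L)   # 3 * (C(9,2) - 9)
  expect_identical(unname(counts[["G1_inter_subtype"]]), 243L)  # 3 * 81
  expect_identical(sum(counts), 351L)                      # partition
  # unannotated sample -> error
  cs$sample_a[1] <- "ghost"
  expect_error(assign_groups(cs, ann), "ghost")
})

test_that("bayes misclassification matches hand arithmetic and boundary behavior", {
  # indistinguishable distributions, equal priors -> 0.5
  v <- c(0.1, 0.4, 0.4, 0.8)
  expect_equal(bayes_misclassification(v, v, bin_width = 0.1)$probability, 0.5)
  # disjoint supports -> 0
  expect_equal(bayes_misclassification(c(0.1, 0.2), c(0.8, 0.9),
                                       bin_width = 0.1)$probability, 0)
  # two-bin hand case -> 1/3
  res <- bayes_misclassification(c(0.1, 0.2), c(0.2, 0.9), breaks = c(0, 0.5, 1))
  expect_equal(res$probability, 1 / 3)
  expect_equal(sum(res$per_bin_contribution), res$probability)
  expect_error(bayes_misclassification(numeric(0), c(1)), "non-empty")
})

test_that("misclassification probability stays within [0, 0.5] under equal priors", {
  set.seed(31)
  for (i in 1:20) {
    g1 <- runif(30, -1, 1)
    g2 <- runif(30, -1, 1)
    p <- bayes_misclassification(g1, g2, bin_width = 0.05)$probability
    expect_gte(p, 0)
    expect_lte(p, 0.5 + 1e-12)
  }
})

test_that("one-sided wilcoxon matches enumeration and is monotone in shift", {
  expect_equal(compare_groups_wilcoxon(c(3, 4), c(1, 2)), 1 / 6)
  expect_gte(compare_groups_wilcoxon(c(1, 2, 3), c(1, 2, 3) + 1e-9), 0.5)
  set.seed(41)
  for (i in 1:10) {
    high <- rnorm(5); low <- rnorm(6)
    expect_equal(compare_groups_wilcoxon(high, low),
                 oracle_wilcoxon_exact(high, low), tolerance = 1e-12)
    # shifting the high group up never increases p
    p0 <- compare_groups_wilcoxon(high, low)
    p1 <- compare_groups_wilcoxon(high + 0.5, low)
    expect_lte(p1, p0 + 1e-12)
  }
  expect_error(compare_groups_wilcoxon(numeric(0), 1), "non-empty")
})

test_that("exact and approximate wilcoxon paths agree at combined n = 12", {
  set.seed(51)
  for (i in 1:20) {
    high <- rnorm(6); low <- rnorm(6) - 0.4
    exact <- compare_groups_wilcoxon(high, low)
    approx <- suppressWarnings(stats::wilcox.test(
      high, low, alternative = "greater", exact = FALSE, correct = TRUE))$p.value
    expect_lt(abs(exact - approx), 0.01)
  }
})

test_that("heterogeneity report summarizes groups and survives missing ones", {
  gen <- generate_expression(cohort_config(
    n_features = 120, sigma_patient = 0.9, sigma_subtype = 0.3,
    presence_dropout = c(subtype = 0, patient = 0, location = 0), seed = 8))
  pairs <- assign_groups(pairwise_correlations(gen$matrix, method = "spearman"),
                         gen$annotation)
  rep_ <- heterogeneity_report(pairs, bin_width = 0.02)
  expect_gt(rep_$spearman$medians[["G2"]], rep_$spearman$medians[["G1"]])
  expect_lt(rep_$spearman$wilcoxon[["G2_gt_G1"]], 0.05)
  expect_true(is.na(rep_$spearman$wilcoxon[["G3_gt_G2"]]))

  # single-patient input: G1 comparisons unavailable, no crash
  keep <- pairs[grepl("^P1_", pairs$sample_a) & grepl("^P1_", pairs$sample_b), ]
  solo <- heterogeneity_report(keep, bin_width = 0.02)
  expect_true(is.na(solo$spearman$wilcoxon[["G2_gt_G1"]]))
  expect_true(is.na(solo$spearman$misclassification))

  # JSON round trip of the summary equals the in-memory result
  dir <- withr::local_tempdir()
  write_heterogeneity_report(rep_, dir)
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$spearman$misclassification, rep_$spearman$misclassification)
  expect_equal(js$spearman$wilcoxon$G2_gt_G1,
               unname(rep_$spearman$wilcoxon[["G2_gt_G1"]]))
  expect_equal(js$spearman$medians$G2, unname(rep_$spearman$medians[["G2"]]))
})

test_that("pca embedding is a faithful rotation with fixed signs", {
  set.seed(61)
  m <- matrix(exp(rnorm(120, 12, 1)), 20, 6,
              dimnames = list(sprintf("f%d", 1:20), sprintf("s%d", 1:6)))
  m[, 4] <- m[, 3]  # duplicated sample
  emb <- pca_embedding(make_matrix(m), n_components = 3)
  expect_equal(emb$coordinates["s3", ], emb$coordinates["s4", ])
  # reconstruction from all components equals the standardized input
  recon <- emb$scores_full %*% t(emb$loadings)
  expect_equal(recon, emb$standardized, tolerance = 1e-8)
  # variance explained is non-increasing
  expect_true(all(diff(emb$var_explained) <= 1e-12))
  # sign convention: largest-|loading| entry positive
  for (k in seq_len(ncol(emb$loadings))) {
    l <- emb$loadings[, k]
    expect_gte(l[which.max(abs(l))], 0)
  }
  expect_error(pca_embedding(make_matrix(m[, 1:2]), n_components = 3), "fewer samples")
})
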