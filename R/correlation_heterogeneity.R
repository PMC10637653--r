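# Correlation-group heterogeneity: all pairwise sample correlations,
# labeled intra-patient (Group 2), inter-patient intra-subtype /
# inter-subtype (Group 1), and noise-control (Group 3), compared by
# one-sided Wilcoxon tests and by a binned Bayesian misclassification
# probability.

CORR_GROUPS <- c("G1_intra_subtype", "G1_inter_subtype", "G2_intra_patient",
                 "G3_noise")

#' Pairwise sample correlations
#'
#' Computes Spearman and/or Pearson correlation for every unordered pair of
#' samples. Under the default missing policy `"zero"`, unobserved
#' intensities are treated as 0 over the union of features observed in at
#' least one sample of the pair; `"pairwise"` restricts each pair to its
#' complete features.
#'
#' @param matrix An [expression_matrix()].
#' @param method `"spearman"`, `"pearson"` or `"both"`.
#' @param missing_policy `"zero"` (default) or `"pairwise"`.
#' @param log2_transform Compute Pearson on `log2(x+1)` instead of raw
#'   intensities (Spearman is rank-based and unaffected).
#' @return Data frame of class `correlation_set`: `sample_a`, `sample_b`,
#'   `method`, `r`.
#' @export
pairwise_correlations <- function(matrix, method = c("both", "spearman", "pearson"),
                                  missing_policy = c("zero", "pairwise"),
                                  log2_transform = FALSE) {
  method <- match.arg(method)
  missing_policy <- match.arg(missing_policy)
  methods <- if (method == "both") c("spearman", "pearson") else method
  ns <- ncol(matrix)
  if (ns < 2) stop("need at least two samples")
  ids <- colnames(matrix)
  vals <- unclass(matrix)
  attr(vals, "kind") <- NULL

  out <- list()
  for (i in seq_len(ns - 1)) {
    for (j in seq((i + 1), ns)) {
      x <- vals[, i]
      y <- vals[, j]
      if (missing_policy == "zero") {
        keep <- !(is.na(x) & is.na(y))
        x <- x[keep]; y <- y[keep]
        x[is.na(x)] <- 0
        y[is.na(y)] <- 0
      } else {
        keep <- !is.na(x) & !is.na(y)
        x <- x[keep]; y <- y[keep]
      }
      if (length(x) < 3) {
        stop(sprintf("pair (%s, %s): fewer than 3 usable features", ids[i], ids[j]))
      }
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        stop(sprintf("pair (%s, %s): constant profile, correlation undefined",
                     ids[i], ids[j]))
      }
      for (m in methods) {
        xx <- x; yy <- y
        if (m == "pearson" && log2_transform) {
          xx <- log2(xx + 1); yy <- log2(yy + 1)
        }
        r <- stats::cor(xx, yy, method = m)
        out[[length(out) + 1L]] <- data.frame(
          sample_a = ids[i], sample_b = ids[j], method = m, r = r,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("correlation_set", "data.frame")
  res
}

#' Label correlation pairs by heterogeneity group
#'
#' Pairs of samples from the same patient form Group 2 (intra-patient);
#' pairs from different patients of the same subtype form Group 1
#' intra-subtype; pairs across subtypes form Group 1 inter-subtype; pairs
#' of noise-control replicates form Group 3. A pair mixing a noise-control
#' replicate with a tumor sample falls across subtypes and is labeled
#' inter-subtype, so the four labels always partition the pair set.
#'
#' @param pairs A `correlation_set` from [pairwise_correlations()].
#' @param annotation A [sample_annotation()] covering every sample.
#' @return `pairs` with an added `group` column.
#' @export
assign_groups <- function(pairs, annotation) {
  check_samples_annotated(unique(c(pairs$sample_a, pairs$sample_b)), annotation)
  pat <- stats::setNames(annotation$patient, annotation$sample)
  sub <- stats::setNames(annotation$subtype, annotation$sample)
  pa <- pat[pairs$sample_a]; pb <- pat[pairs$sample_b]
  sa <- sub[pairs$sample_a]; sb <- sub[pairs$sample_b]
  group <- ifelse(sa == "noise_control" & sb == "noise_control", "G3_noise",
           ifelse(pa == pb, "G2_intra_patient",
           ifelse(sa == sb, "G1_intra_subtype", "G1_inter_subtype")))
  pairs$group <- unname(group)
  class(pairs) <- c("correlation_set", "data.frame")
  pairs
}

#' Binned Bayesian misclassification probability
#'
#' Estimates the probability that a correlation value drawn from the
#' intra-patient distribution (Group 2) would be attributed to the
#' inter-patient distribution (Group 1). With equal priors, each bin `b`
#' contributes `d2(b) * d1(b) / (d1(b) + d2(b))` where `d1`, `d2` are the
#' per-bin probability masses of the two groups; contributions where both
#' masses vanish are 0. Identical distributions give 0.5, disjoint
#' supports give 0.
#'
#' @param values_g1,values_g2 Numeric vectors of correlation values for the
#'   reference (Group 1) and query (Group 2) distributions.
#' @param bin_width Bin width over the observed combined range (default
#'   0.01). Ignored when `breaks` is given.
#' @param breaks Optional explicit increasing bin edges covering all
#'   values; bins are left-closed, the last bin closed on both sides.
#' @return A list of class `misclassification_result` with `probability`,
#'   `bin_edges`, `per_bin_contribution`.
#' @export
bayes_misclassification <- function(values_g1, values_g2, bin_width = 0.01,
                                    breaks = NULL) {
  if (length(values_g1) == 0 || length(values_g2) == 0) {
    stop("both groups must be non-empty")
  }
  all_v <- c(values_g1, values_g2)
  if (is.null(breaks)) {
    lo <- floor(min(all_v) / bin_width) * bin_width
    hi <- ceiling(max(all_v) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    breaks <- seq(lo, hi, by = bin_width)
    if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  }
  if (min(all_v) < breaks[1] || max(all_v) > breaks[length(breaks)]) {
    stop("breaks do not cover the observed values")
  }
  bin_of <- function(v) {
    b <- findInterval(v, breaks, rightmost.closed = TRUE)
    pmin(pmax(b, 1L), length(breaks) - 1L)
  }
  nb <- length(breaks) - 1L
  d1 <- tabulate(bin_of(values_g1), nb) / length(values_g1)
  d2 <- tabulate(bin_of(values_g2), nb) / length(values_g2)
  denom <- d1 + d2
  post_g1 <- ifelse(denom > 0, d1 / denom, 0)
  contrib <- d2 * post_g1
  structure(list(probability = sum(contrib), bin_edges = breaks,
                 per_bin_contribution = contrib),
            class = "misclassification_result")
}

#' One-sided Wilcoxon rank-sum comparison of correlation groups
#'
#' Tests the alternative that `values_high` is stochastically larger than
#' `values_low`. The exact null distribution is used when the combined
#' sample size is at most 12 and there are no ties; otherwise the normal
#' approximation with continuity correction and mid-ranks is used.
#'
#' @param values_high,values_low Numeric vectors.
#' @return The one-sided p-value.
#' @export
compare_groups_wilcoxon <- function(values_high, values_low) {
  if (length(values_high) == 0 || length(values_low) == 0) {
    stop("both groups must be non-empty")
  }
  n <- length(values_high) + length(values_low)
  ties <- anyDuplicated(c(values_high, values_low)) > 0
  use_exact <- n <= 12 && !ties
  res <- suppressWarnings(stats::wilcox.test(
    values_high, values_low, alternative = "greater",
    exact = use_exact, correct = TRUE))
  unname(res$p.value)
}

#' Summarize grouped correlations into a heterogeneity report
#'
#' Produces, per correlation method: shared-binning group histograms,
#' one-sided Wilcoxon p-values for the ordered comparisons G2 > G1,
#' G3 > G2 and G3 > G1, and the Group-2-vs-Group-1 misclassification
#' probability. Comparisons whose groups are absent are reported as
#' unavailable (`NA`).
#'
#' @param groups A grouped `correlation_set` (see [assign_groups()]).
#' @param bin_width Histogram and misclassification bin width.
#' @return A list of class `heterogeneity_report` with one entry per
#'   method: `histogram` (data frame bin_lo, bin_hi, and one density
#'   column per group), `medians`, `wilcoxon` (named p-values), and
#'   `misclassification`.
#' @export
heterogeneity_report <- function(groups, bin_width = 0.01) {
  if (is.null(groups$group)) stop("correlations are not grouped; run assign_groups()")
  out <- list()
  for (m in unique(groups$method)) {
    g <- groups[groups$method == m, , drop = FALSE]
    g1 <- g$r[g$group %in% c("G1_intra_subtype", "G1_inter_subtype")]
    g2 <- g$r[g$group == "G2_intra_patient"]
    g3 <- g$r[g$group == "G3_noise"]

    lo <- floor(min(g$r) / bin_width) * bin_width
    hi <- ceiling(max(g$r) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    brk <- seq(lo, hi, by = bin_width)
    if (brk[length(brk)] < hi) brk <- c(brk, hi)
    hist_df <- data.frame(bin_lo = brk[-length(brk)], bin_hi = brk[-1])
    for (grp in CORR_GROUPS) {
      v <- g$r[g$group == grp]
      dens <- if (length(v) > 0) {
        b <- pmin(pmax(findInterval(v, brk, rightmost.closed = TRUE), 1L),
                  length(brk) - 1L)
        tabulate(b, length(brk) - 1L) / length(v)
      } else rep(NA_real_, length(brk) - 1L)
      hist_df[[grp]] <- dens
    }

    wpv <- c(G2_gt_G1 = NA_real_, G3_gt_G2 = NA_real_, G3_gt_G1 = NA_real_)
    if (length(g1) > 0 && length(g2) > 0) wpv[["G2_gt_G1"]] <- compare_groups_wilcoxon(g2, g1)
    if (length(g2) > 0 && length(g3) > 0) wpv[["G3_gt_G2"]] <- compare_groups_wilcoxon(g3, g2)
    if (length(g1) > 0 && length(g3) > 0) wpv[["G3_gt_G1"]] <- compare_groups_wilcoxon(g3, g1)

    mis <- if (length(g1) > 0 && length(g2) > 0) {
      bayes_misclassification(g1, g2, bin_width = bin_width)$probability
    } else NA_real_

    out[[m]] <- list(
      histogram = hist_df,
      medians = c(G1 = if (length(g1)) stats::median(g1) else NA_real_,
                  G2 = if (length(g2)) stats::median(g2) else NA_real_,
                  G3 = if (length(g3)) stats::median(g3) else NA_real_),
      wilcoxon = wpv,
      misclassification = mis)
  }
  structure(out, class = "heterogeneity_report", bin_width = bin_width)
}

#' Write a heterogeneity report to TSV + JSON
#'
#' Histograms go to `<method>_histogram.tsv`; medians, Wilcoxon p-values
#' and misclassification probabilities go to `summary.json`.
#'
#' @param report A [heterogeneity_report()].
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_heterogeneity_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  summary <- list()
  for (m in names(report)) {
    p <- file.path(dir, paste0(m, "_histogram.tsv"))
    utils::write.table(report[[m]]$histogram, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    paths <- c(paths, p)
    summary[[m]] <- list(medians = as.list(report[[m]]$medians),
                         wilcoxon = as.list(report[[m]]$wilcoxon),
                         misclassification = report[[m]]$misclassification)
  }
  jp <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, jp, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(paths, jp))
}

#' PCA embedding of sample profiles
#'
#' Projects samples onto the top principal components of the standardized
#' `log2(x + 1)` matrix (missing values treated as unobserved, i.e. 0
#' intensity; zero-variance features dropped before standardization). Each
#' component's sign is fixed by making its largest-magnitude loading
#' positive.
#'
#' @param matrix An [expression_matrix()].
#' @param n_components Number of components to return (<= number of samples).
#' @return A list of class `pca_embedding`: `coordinates` (samples x
#'   components), `loadings`, `sdev`, `var_explained`, and the
#'   standardized input `standardized` (samples x features).
#' @export
pca_embedding <- function(matrix, n_components = 3) {
  ns <- ncol(matrix)
  if (ns < n_components) stop("fewer samples than requested components")
  x <- unclass(matrix)
  attr(x, "kind") <- NULL
  x[is.na(x)] <- 0
  lx <- log2(x + 1)
  keep <- apply(lx, 1, stats::sd) > 0
  z <- t(scale(t(lx[keep, , drop = FALSE])))  # standardize per feature
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  k <- ncol(pc$rotation)
  # sign convention: largest-|loading| entry positive per component
  for (i in seq_len(k)) {
    load <- pc$rotation[, i]
    if (load[which.max(abs(load))] < 0) {
      pc$rotation[, i] <- -load
      pc$x[, i] <- -pc$x[, i]
    }
  }
  var_expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    coordinates = pc$x[, seq_len(n_components), drop = FALSE],
    loadings = pc$rotation, sdev = pc$sdev, var_explained = var_expl,
    scores_full = pc$x, standardized = t(z)),
    class = "pca_embedding")
}
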