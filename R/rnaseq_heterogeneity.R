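# Intra-patient heterogeneous-gene screening on bulk RNA-seq counts:
# CPM normalization, low-expression filtering, per-patient maximum
# pairwise |log2 fold change|, cross-patient overlap selection, and a
# permutation test for the overlap size.

#' Counts-per-million normalization
#'
#' Scales each sample's counts so the column sums to one million.
#'
#' @param counts An [expression_matrix()] of kind `raw_counts`.
#' @return An [expression_matrix()] of kind `cpm`.
#' @export
cpm_normalize <- function(counts) {
  if (expression_kind(counts) != "raw_counts") {
    stop("cpm_normalize expects raw_counts, got ", expression_kind(counts))
  }
  x <- unclass(counts)
  attr(x, "kind") <- NULL
  libsize <- colSums(x, na.rm = TRUE)
  if (any(libsize <= 0)) {
    stop("zero-sum column: ", colnames(x)[which(libsize <= 0)[1L]])
  }
  cpm <- sweep(x, 2, libsize, "/") * 1e6
  expression_matrix(cpm, "cpm")
}

#' Filter genes with low expression everywhere
#'
#' Removes genes whose CPM is below `threshold` in every sample; a gene
#' reaching the threshold in at least one sample is kept.
#'
#' @param cpm An [expression_matrix()] of kind `cpm`.
#' @param threshold CPM threshold (default 0.5).
#' @return The filtered matrix (kind `cpm`).
#' @export
filter_low_expression <- function(cpm, threshold = 0.5) {
  if (expression_kind(cpm) != "cpm") stop("filter expects cpm matrix")
  x <- unclass(cpm)
  attr(x, "kind") <- NULL
  keep <- apply(x, 1, function(v) any(!is.na(v) & v >= threshold))
  expression_matrix(x[keep, , drop = FALSE], "cpm")
}

#' Per-gene, per-patient maximum pairwise fold change
#'
#' For each gene and patient, the maximum over all pairs of the patient's
#' samples of `|log2((x_i + c) / (x_j + c))|`, the intra-patient
#' heterogeneity score.
#'
#' @param cpm An [expression_matrix()] of kind `cpm`.
#' @param annotation A [sample_annotation()]; every patient needs >= 2
#'   samples.
#' @param pseudocount Added to both sides of the ratio (default 1 CPM);
#'   0 is allowed when all values are positive.
#' @return A numeric gene x patient matrix of max |log2 FC|.
#' @export
max_pairwise_fc <- function(cpm, annotation, pseudocount = 1) {
  if (expression_kind(cpm) != "cpm") stop("max_pairwise_fc expects cpm matrix")
  check_samples_annotated(colnames(cpm), annotation)
  ann <- annotation[match(colnames(cpm), annotation$sample), , drop = FALSE]
  x <- unclass(cpm)
  attr(x, "kind") <- NULL
  if (pseudocount == 0 && any(is.na(x) | x <= 0)) {
    stop("pseudocount 0 requires strictly positive values")
  }
  x[is.na(x)] <- 0
  lx <- log2(x + pseudocount)
  patients <- unique(ann$patient)
  out <- matrix(0, nrow(x), length(patients),
                dimnames = list(rownames(x), patients))
  for (p in patients) {
    cols <- which(ann$patient == p)
    if (length(cols) < 2) stop("patient '", p, "' has fewer than 2 samples")
    cmb <- utils::combn(cols, 2)
    mx <- rep(0, nrow(x))
    for (k in seq_len(ncol(cmb))) {
      mx <- pmax(mx, abs(lx[, cmb[1, k]] - lx[, cmb[2, k]]))
    }
    out[, p] <- mx
  }
  out
}

#' Select genes heterogeneous in multiple patients
#'
#' A gene enters a patient's list when its max |log2 FC| reaches
#' `fc_threshold`; genes listed by at least `min_patients` patients are
#' selected.
#'
#' @param per_patient_fc Gene x patient matrix from [max_pairwise_fc()].
#' @param fc_threshold Threshold on max |log2 FC| (default 2, i.e. 4-fold).
#' @param min_patients Minimum number of listing patients (default 2).
#' @return A data frame of class `heterogeneous_genes`: `gene_id`,
#'   `max_abs_log2_fc` (maximum across patients), `n_patients_listed`,
#'   `selected`, plus one `fc_<patient>` column per patient.
#' @export
select_heterogeneous <- function(per_patient_fc, fc_threshold = 2,
                                 min_patients = 2) {
  if (ncol(per_patient_fc) < min_patients) {
    stop("need at least min_patients patients")
  }
  listed <- per_patient_fc >= fc_threshold
  n_listed <- rowSums(listed)
  res <- data.frame(gene_id = rownames(per_patient_fc),
                    max_abs_log2_fc = apply(per_patient_fc, 1, max),
                    n_patients_listed = as.integer(n_listed),
                    selected = n_listed >= min_patients,
                    stringsAsFactors = FALSE)
  for (p in colnames(per_patient_fc)) {
    res[[paste0("fc_", p)]] <- per_patient_fc[, p]
  }
  rownames(res) <- NULL
  class(res) <- c("heterogeneous_genes", "data.frame")
  res
}

#' Permutation significance of a cross-patient list overlap
#'
#' Under the null, each patient's gene list is an independent uniform draw
#' of its observed size from the universe. The statistic is the number of
#' genes appearing in at least `min_patients` lists;
#' `p = (1 + #{perm >= observed}) / (1 + n_perm)`.
#'
#' @param list_sizes Integer vector of per-patient list sizes.
#' @param universe_size Number of genes in the universe.
#' @param observed_overlap Observed number of genes in >= `min_patients`
#'   lists.
#' @param n_perm Number of permutations.
#' @param seed Integer RNG seed.
#' @param min_patients Overlap threshold (default 2).
#' @return A list with `p_value`, `observed`, `null_mean`, `null_sd`.
#' @export
overlap_significance <- function(list_sizes, universe_size, observed_overlap,
                                 n_perm = 10000, seed = 1, min_patients = 2) {
  if (any(list_sizes > universe_size)) stop("list size exceeds universe")
  max_possible <- floor(sum(list_sizes) / min_patients)
  if (observed_overlap > max_possible) {
    stop("observed overlap exceeds the largest possible overlap")
  }
  set.seed(as.integer(seed))
  stat <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    tally <- integer(universe_size)
    for (sz in list_sizes) {
      idx <- sample.int(universe_size, sz)
      tally[idx] <- tally[idx] + 1L
    }
    stat[b] <- sum(tally >= min_patients)
  }
  list(p_value = (1 + sum(stat >= observed_overlap)) / (1 + n_perm),
       observed = observed_overlap,
       null_mean = mean(stat), null_sd = stats::sd(stat))
}

#' Exact overlap p-value by exhaustive enumeration
#'
#' Enumerates all combinations of per-patient lists over a small universe
#' and returns the exact probability that at least `observed_overlap`
#' genes appear in >= `min_patients` lists. Intended as a validation path
#' for [overlap_significance()]; the number of combinations must stay
#' small.
#'
#' @inheritParams overlap_significance
#' @param max_combinations Guard on the total enumeration size.
#' @return The exact p-value.
#' @export
overlap_significance_exact <- function(list_sizes, universe_size,
                                       observed_overlap, min_patients = 2,
                                       max_combinations = 1e6) {
  n_comb <- prod(choose(universe_size, list_sizes))
  if (n_comb > max_combinations) {
    stop("enumeration too large (", format(n_comb), " combinations)")
  }
  sets <- lapply(list_sizes, function(sz)
    utils::combn(universe_size, sz, simplify = FALSE))
  idx <- lapply(sets, seq_along)
  grid <- expand.grid(idx, KEEP.OUT.ATTRS = FALSE)
  hits <- 0L
  for (r in seq_len(nrow(grid))) {
    tally <- integer(universe_size)
    for (j in seq_along(sets)) {
      members <- sets[[j]][[grid[r, j]]]
      tally[members] <- tally[members] + 1L
    }
    if (sum(tally >= min_patients) >= observed_overlap) hits <- hits + 1L
  }
  hits / nrow(grid)
}

#' Export a ranked heterogeneous-gene list
#'
#' Genes ranked by number of listing patients, then maximum fold change,
#' then gene id (so ranking is stable under input permutation). Writes a
#' plain one-column list and a two-column (gene, score) table.
#'
#' @param results A `heterogeneous_genes` data frame (see
#'   [select_heterogeneous()]); only selected genes are exported unless
#'   `selected_only = FALSE`.
#' @param path Base output path; the one-column file gets `path`, the
#'   two-column file gets `<path>.scores.tsv`.
#' @param selected_only Export only selected genes (default `TRUE`).
#' @return Paths written, invisibly.
#' @export
export_gene_list <- function(results, path, selected_only = TRUE) {
  if (nrow(results) == 0) stop("no results to export")
  r <- if (selected_only) results[results$selected, , drop = FALSE] else results
  ord <- order(-r$n_patients_listed, -r$max_abs_log2_fc, r$gene_id)
  r <- r[ord, , drop = FALSE]
  writeLines(r$gene_id, path)
  scores <- file.path(paste0(path, ".scores.tsv"))
  utils::write.table(
    data.frame(gene = r$gene_id, score = r$max_abs_log2_fc),
    scores, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, scores))
}
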