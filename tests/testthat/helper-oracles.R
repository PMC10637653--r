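# Independent oracles used to validate the package's implementations.
# These deliberately take different routes than the package code.

# Rank correlation straight from the definition: Pearson moment formula
# applied to mid-ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Exact one-sided Wilcoxon rank-sum p-value by enumerating every
# assignment of the combined ranks to the "high" group.
oracle_wilcoxon_exact <- function(high, low) {
  comb <- c(high, low)
  ranks <- rank(comb)
  n_high <- length(high)
  observed <- sum(ranks[seq_len(n_high)])
  picks <- utils::combn(length(comb), n_high)
  stat <- apply(picks, 2, function(idx) sum(ranks[idx]))
  mean(stat >= observed)
}

# Slice counts by per-feature membership patterns: for each feature,
# enumerate which samples contain it, then test each slice predicate
# directly on that set.
oracle_decompose <- function(presence, annotation) {
  ann <- annotation[match(colnames(presence), annotation$sample), ]
  members <- apply(presence, 1, function(row) colnames(presence)[row],
                   simplify = FALSE)
  holds_all <- function(samples) {
    vapply(members, function(m) all(samples %in% m), logical(1))
  }
  out <- list(global = sum(holds_all(ann$sample)))
  out$subtype <- sapply(unique(ann$subtype), function(s)
    sum(holds_all(ann$sample[ann$subtype == s])))
  out$patient <- sapply(unique(ann$patient), function(p)
    sum(holds_all(ann$sample[ann$patient == p])))
  pair_counts <- list()
  uniq_counts <- list()
  for (p in unique(ann$patient)) {
    locs <- sort(ann$location[ann$patient == p])
    if (length(locs) >= 2) {
      cmb <- utils::combn(locs, 2)
      for (k in seq_len(ncol(cmb))) {
        s <- ann$sample[ann$patient == p & ann$location %in% cmb[, k]]
        pair_counts[[paste(p, cmb[1, k], cmb[2, k])]] <- sum(holds_all(s))
      }
    }
    for (l in locs) {
      s_here <- ann$sample[ann$patient == p & ann$location == l]
      s_other <- ann$sample[ann$patient == p & ann$location != l]
      uniq_counts[[paste(p, l)]] <- sum(vapply(members, function(m)
        all(s_here %in% m) && !any(s_other %in% m), logical(1)))
    }
  }
  out$pairs <- unlist(pair_counts)
  out$unique <- unlist(uniq_counts)
  out
}

# Shannon entropy (base 2) of a probability vector, summed over support.
oracle_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Tiny two-subtype / two-patient / three-location annotation (12 samples).
small_annotation <- function(locations = 3) {
  rows <- expand.grid(loc = seq_len(locations), pat = 1:4,
                      KEEP.OUT.ATTRS = FALSE)
  sample_annotation(data.frame(
    sample = sprintf("P%d_L%d", rows$pat, rows$loc),
    patient = sprintf("P%d", rows$pat),
    subtype = ifelse(rows$pat <= 2, "infiltrative", "nodular"),
    location = sprintf("L%d", rows$loc), stringsAsFactors = FALSE))
}

# Random presence matrix over an annotation.
random_presence <- function(annotation, n_features = 100, p = 0.7, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n_features * nrow(annotation)) < p, n_features,
              nrow(annotation),
              dimnames = list(sprintf("F%03d", seq_len(n_features)),
                              annotation$sample))
  structure(m, class = c("presence_matrix", class(m)))
}
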