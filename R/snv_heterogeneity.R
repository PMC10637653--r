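# Jensen-Shannon allelic heterogeneity: per genome position, compare the
# expressed-allele distributions of intra-patient sample pairs and call
# positions whose JS distance exceeds a threshold.

#' Expressed-allele frequencies from base counts
#'
#' @param counts Four nonnegative integers (A, C, G, T) with positive sum.
#' @return Probability vector over A, C, G, T (no pseudocount).
#' @export
allele_frequencies <- function(counts) {
  if (length(counts) != 4 || any(counts < 0)) {
    stop("counts must be 4 nonnegative integers (A, C, G, T)")
  }
  tot <- sum(counts)
  if (tot < 1) stop("zero total coverage: frequencies undefined")
  counts / tot
}

#' Jensen-Shannon distance between probability vectors
#'
#' The square root of the Jensen-Shannon divergence with base-2
#' logarithms (`0 * log 0 := 0`), a symmetric metric bounded in \[0, 1\].
#'
#' @param p,q Probability vectors of equal length (sums within 1e-9 of 1).
#' @param as_divergence Return the divergence instead of its square root.
#' @return A number in \[0, 1\].
#' @export
js_distance <- function(p, q, as_divergence = FALSE) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9 ||
      any(p < 0) || any(q < 0)) {
    stop("p and q must be probability vectors")
  }
  m <- (p + q) / 2
  plogp <- function(x) ifelse(x > 0, x * log2(x), 0)
  h <- function(x) -sum(plogp(x))
  jsd <- h(m) - (h(p) + h(q)) / 2
  jsd <- min(max(jsd, 0), 1)  # clamp tiny negative rounding
  if (as_divergence) jsd else sqrt(jsd)
}

#' Call positions with divergent intra-patient allele distributions
#'
#' For every genome position and every pair of samples from the same
#' patient with coverage at least `min_cov` on both sides, computes the
#' Jensen-Shannon distance between the two expressed-allele distributions;
#' a pair is called when the distance exceeds `threshold`. A per-position,
#' per-patient summary reports the maximum pairwise distance.
#'
#' @param table An [allele_count_table()].
#' @param annotation A [sample_annotation()] covering every sample.
#' @param min_cov Minimum reads per sample per position (default 10).
#' @param threshold JS distance call threshold (default 0.6).
#' @return A list of class `position_calls` with data frames `calls` (one
#'   row per position x intra-patient pair: `chrom`, `pos`, `patient`,
#'   `sample_a`, `sample_b`, `js_distance`, `cov_a`, `cov_b`, `called`),
#'   `summary` (max pairwise distance per position and patient), and
#'   `skipped` (pairs failing the coverage filter).
#' @export
call_positions <- function(table, annotation, min_cov = 10, threshold = 0.6) {
  check_samples_annotated(unique(table$sample), annotation)
  pat <- stats::setNames(annotation$patient, annotation$sample)
  df <- as.data.frame(table)
  df$patient <- unname(pat[df$sample])
  df$coverage <- df$A + df$C + df$G + df$T

  calls <- list(); skipped <- list()
  for (key in unique(paste(df$chrom, df$pos, df$patient, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    sub <- df[df$chrom == parts[1] & df$pos == as.integer(parts[2]) &
                df$patient == parts[3], , drop = FALSE]
    if (nrow(sub) < 2) next
    cmb <- utils::combn(nrow(sub), 2)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1, k]; j <- cmb[2, k]
      row <- data.frame(chrom = sub$chrom[1], pos = sub$pos[1],
                        patient = sub$patient[1],
                        sample_a = sub$sample[i], sample_b = sub$sample[j],
                        cov_a = sub$coverage[i], cov_b = sub$coverage[j],
                        stringsAsFactors = FALSE)
      if (sub$coverage[i] < min_cov || sub$coverage[j] < min_cov) {
        skipped[[length(skipped) + 1L]] <- row
        next
      }
      p <- allele_frequencies(as.numeric(sub[i, c("A", "C", "G", "T")]))
      q <- allele_frequencies(as.numeric(sub[j, c("A", "C", "G", "T")]))
      row$js_distance <- js_distance(p, q)
      row$called <- row$js_distance > threshold
      calls[[length(calls) + 1L]] <- row
    }
  }
  empty_call <- data.frame(chrom = character(), pos = integer(),
                           patient = character(), sample_a = character(),
                           sample_b = character(), cov_a = integer(),
                           cov_b = integer(), js_distance = numeric(),
                           called = logical(), stringsAsFactors = FALSE)
  calls_df <- if (length(calls)) do.call(rbind, calls) else empty_call
  calls_df <- calls_df[order(calls_df$chrom, calls_df$pos, calls_df$patient,
                             calls_df$sample_a, calls_df$sample_b), ,
                       drop = FALSE]
  rownames(calls_df) <- NULL

  if (nrow(calls_df) > 0) {
    key <- paste(calls_df$chrom, calls_df$pos, calls_df$patient, sep = "\r")
    agg <- tapply(calls_df$js_distance, key, max)
    parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
    summary_df <- data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
                             patient = parts[, 3],
                             max_js_distance = as.numeric(agg),
                             called = as.numeric(agg) > threshold,
                             stringsAsFactors = FALSE)
    summary_df <- summary_df[order(summary_df$chrom, summary_df$pos,
                                   summary_df$patient), , drop = FALSE]
    rownames(summary_df) <- NULL
  } else {
    summary_df <- data.frame(chrom = character(), pos = integer(),
                             patient = character(),
                             max_js_distance = numeric(), called = logical(),
                             stringsAsFactors = FALSE)
  }
  skipped_df <- if (length(skipped)) do.call(rbind, skipped) else
    empty_call[, c("chrom", "pos", "patient", "sample_a", "sample_b",
                   "cov_a", "cov_b")]
  structure(list(calls = calls_df, summary = summary_df,
                 skipped = skipped_df, threshold = threshold,
                 min_cov = min_cov),
            class = "position_calls")
}

#' Write position calls to TSV
#'
#' One row per position x intra-patient pair, sorted by chromosome and
#' position.
#'
#' @param calls A `position_calls` object or its `calls` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
report_calls <- function(calls, path) {
  df <- if (inherits(calls, "position_calls")) calls$calls else calls
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
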