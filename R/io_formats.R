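#' @keywords internal
"_PACKAGE"

# Recognized histological subtypes plus the LC-MS noise-control pseudo-group.
SUBTYPE_LEVELS <- c("infiltrative", "superficial", "nodular", "noise_control", "other")

EXPRESSION_KINDS <- c("lfq_intensity", "raw_counts", "cpm")

#' Construct an expression matrix
#'
#' Wraps a numeric feature x sample matrix together with its measurement kind
#' (label-free quantitation intensity, raw read counts, or counts per
#' million). Missing values (`NA`) are allowed and mean "not observed", which
#' is distinct from an observed zero.
#'
#' @param values Numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids). Present values must be >= 0.
#' @param kind One of `"lfq_intensity"`, `"raw_counts"`, `"cpm"`.
#' @return A numeric matrix of class `expr_matrix` with a `kind` attribute.
#' @export
expression_matrix <- function(values, kind) {
  kind <- match.arg(kind, EXPRESSION_KINDS)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have rownames (feature ids) and colnames (sample ids)")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    stop("duplicate feature id: ", dup)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1L]
    stop("duplicate sample id: ", dup)
  }
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("negative value at feature '%s', sample '%s'",
                 rownames(values)[neg[1L, 1L]], colnames(values)[neg[1L, 2L]]))
  }
  structure(values, kind = kind, class = c("expr_matrix", class(values)))
}

#' Measurement kind of an expression matrix
#' @param x An `expr_matrix`.
#' @return The kind string.
#' @export
expression_kind <- function(x) {
  k <- attr(x, "kind")
  if (is.null(k)) stop("not an expression matrix: no `kind` attribute")
  k
}

#' Read a feature x sample expression table from TSV
#'
#' Expects a tab-separated file whose header row holds sample ids (first
#' column is the feature-id column) and whose body holds nonnegative values.
#' Empty cells are read as missing (`NA`), not as zero.
#'
#' @param path Path to the TSV file.
#' @inheritParams expression_matrix
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, kind) {
  kind <- match.arg(kind, EXPRESSION_KINDS)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) {
    stop("malformed header in '", path, "': need a feature column plus >=1 sample column")
  }
  sample_ids <- header[-1L]
  if (any(!nzchar(sample_ids))) stop("malformed header: empty sample id")
  if (anyDuplicated(sample_ids)) {
    stop("malformed header: duplicate sample id '",
         sample_ids[duplicated(sample_ids)][1L], "'")
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          na.strings = "", colClasses = c("character", rep("numeric", length(sample_ids))),
                          quote = "", comment.char = "")
  if (anyDuplicated(df[[1L]])) {
    stop("duplicate feature id '", df[[1L]][duplicated(df[[1L]])][1L], "' in '", path, "'")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  colnames(m) <- sample_ids
  expression_matrix(m, kind)
}

#' Write an expression matrix to TSV
#'
#' Missing values are written as empty fields so that a round trip preserves
#' the missing-vs-zero distinction.
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @param feature_col Name of the feature-id column in the header.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, feature_col = "feature") {
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- feature_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "")
  invisible(path)
}

#' Construct a sample annotation
#'
#' Maps each sample to its patient, histological subtype and sampling
#' location. Noise-control replicates carry the subtype `"noise_control"`
#' and may leave the location blank.
#'
#' @param df Data frame with columns `sample`, `patient`, `subtype`,
#'   `location` (character).
#' @return `df` with class `sample_annotation`.
#' @export
sample_annotation <- function(df) {
  req <- c("sample", "patient", "subtype", "location")
  if (!all(req %in% names(df))) {
    stop("annotation needs columns: ", paste(req, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in req) df[[col]] <- as.character(df[[col]])
  if (anyDuplicated(df$sample)) {
    stop("duplicate sample id '", df$sample[duplicated(df$sample)][1L], "' in annotation")
  }
  bad <- setdiff(unique(df$subtype), SUBTYPE_LEVELS)
  if (length(bad) > 0) {
    stop("unknown subtype '", bad[1L], "'; allowed: ",
         paste(SUBTYPE_LEVELS, collapse = ", "))
  }
  # a patient maps to exactly one subtype
  per_pat <- tapply(df$subtype, df$patient, function(s) length(unique(s)))
  if (any(per_pat > 1L)) {
    stop("patient '", names(per_pat)[per_pat > 1L][1L], "' maps to multiple subtypes")
  }
  non_noise <- df[df$subtype != "noise_control", , drop = FALSE]
  if (nrow(non_noise) > 0 && any(!nzchar(non_noise$location))) {
    stop("non-noise sample '", non_noise$sample[!nzchar(non_noise$location)][1L],
         "' has no location")
  }
  class(df) <- c("sample_annotation", "data.frame")
  df
}

#' Read a sample annotation TSV
#'
#' Columns: `sample`, `patient`, `subtype`, `location` (tab-separated, with
#' header). Subtype strings are validated against the allowed set.
#'
#' @param path Path to the TSV file.
#' @return A [sample_annotation()].
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          na.strings = NULL, colClasses = "character",
                          quote = "", comment.char = "")
  sample_annotation(df)
}

#' Write a sample annotation to TSV
#' @param ann A [sample_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Construct a per-position allele-count table
#'
#' One record per (chromosome, 1-based position, sample) with read counts
#' over the four bases A, C, G, T.
#'
#' @param df Data frame with columns `chrom`, `pos`, `sample`, `A`, `C`,
#'   `G`, `T`.
#' @return `df` with class `allele_count_table`.
#' @export
allele_count_table <- function(df) {
  req <- c("chrom", "pos", "sample", "A", "C", "G", "T")
  if (!all(req %in% names(df))) {
    stop("allele table needs columns: ", paste(req, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$chrom <- as.character(df$chrom)
  df$sample <- as.character(df$sample)
  for (col in c("pos", "A", "C", "G", "T")) {
    v <- df[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v != floor(v))) {
      stop("non-integer value in column '", col, "'")
    }
    df[[col]] <- as.integer(v)
  }
  if (any(df$pos < 1L)) {
    stop("positions are 1-based; found pos ", min(df$pos))
  }
  counts <- as.matrix(df[, c("A", "C", "G", "T")])
  if (any(counts < 0L)) stop("negative allele count")
  key <- paste(df$chrom, df$pos, df$sample, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop(sprintf("duplicate record for %s:%d sample %s",
                 df$chrom[i], df$pos[i], df$sample[i]))
  }
  class(df) <- c("allele_count_table", "data.frame")
  df
}

#' Read an allele-count TSV
#'
#' Columns `chrom`, `pos`, `sample`, `A`, `C`, `G`, `T`; positions are
#' 1-based and strand-collapsed.
#'
#' @param path Path to the TSV file.
#' @return An [allele_count_table()].
#' @export
read_allele_counts <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          quote = "", comment.char = "")
  allele_count_table(df)
}

#' Write an allele-count table to TSV
#' @param tbl An [allele_count_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allele_counts <- function(tbl, path) {
  utils::write.table(as.data.frame(tbl), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Shared guard: every sample id of a matrix/table must be annotated.
check_samples_annotated <- function(sample_ids, annotation) {
  missing <- setdiff(sample_ids, annotation$sample)
  if (length(missing) > 0) {
    stop("sample '", missing[1L], "' not covered by the annotation")
  }
  invisible(TRUE)
}
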