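# Presence/absence calling and the nested intersection (Venn-slice)
# decomposition: which features are shared by all samples, by all samples
# of a subtype, by all locations of a patient, by location pairs, or are
# unique to a single location — plus marker extraction across subtypes and
# the permutation expectation of location-unique features.

#' Call presence/absence from a quantification matrix
#'
#' A feature is present in a sample iff its value is observed and strictly
#' positive (missing and zero both mean "not observed").
#'
#' @param matrix An [expression_matrix()] of kind `lfq_intensity` or `cpm`.
#' @return A logical feature x sample matrix of class `presence_matrix`.
#' @export
call_presence <- function(matrix) {
  kind <- expression_kind(matrix)
  if (!kind %in% c("lfq_intensity", "cpm")) {
    stop("presence calling expects lfq_intensity or cpm, got ", kind)
  }
  x <- unclass(matrix)
  attr(x, "kind") <- NULL
  pres <- !is.na(x) & x > 0
  structure(pres, class = c("presence_matrix", class(pres)))
}

#' Nested intersection decomposition of a presence matrix
#'
#' Counts, at each level of the subtype -> patient -> location hierarchy,
#' the features shared by every sample of the level (cumulative) and the
#' increment over the enclosing level (additional): global shared, per
#' subtype, per patient, per intra-patient location pair, and per-location
#' unique counts (present in that location, absent in the patient's other
#' locations) with location totals.
#'
#' @param presence A `presence_matrix` (see [call_presence()]).
#' @param annotation A [sample_annotation()] covering every sample
#'   (noise-control rows are ignored).
#' @return A list of class `slice_decomposition` with `global_shared` and
#'   data frames `subtypes`, `patients`, `pairs`, `locations`.
#' @export
decompose_presence <- function(presence, annotation) {
  ann <- annotation[annotation$subtype != "noise_control", , drop = FALSE]
  check_samples_annotated(colnames(presence), sample_annotation(as.data.frame(ann)))
  ann <- ann[match(colnames(presence), ann$sample), , drop = FALSE]

  shared_in <- function(samples) {
    as.integer(sum(rowSums(presence[, samples, drop = FALSE]) == length(samples)))
  }

  global_shared <- shared_in(ann$sample)

  subtypes <- unique(ann$subtype)
  sub_df <- data.frame(subtype = subtypes,
                       shared = vapply(subtypes, function(s)
                         shared_in(ann$sample[ann$subtype == s]), integer(1)),
                       stringsAsFactors = FALSE)
  sub_df$additional <- sub_df$shared - global_shared

  patients <- unique(ann$patient)
  pat_sub <- vapply(patients, function(p) unique(ann$subtype[ann$patient == p]), character(1))
  pat_df <- data.frame(patient = patients, subtype = pat_sub,
                       shared = vapply(patients, function(p)
                         shared_in(ann$sample[ann$patient == p]), integer(1)),
                       stringsAsFactors = FALSE)
  pat_df$additional <- pat_df$shared - sub_df$shared[match(pat_df$subtype, sub_df$subtype)]

  pair_rows <- list()
  loc_rows <- list()
  for (p in patients) {
    pa <- ann[ann$patient == p, , drop = FALSE]
    locs <- sort(pa$location)
    if (length(locs) < 2) {
      warning("patient '", p, "' has a single location; pairwise/unique slices empty")
    }
    p_shared <- pat_df$shared[pat_df$patient == p]
    if (length(locs) >= 2) {
      cmb <- utils::combn(locs, 2)
      for (k in seq_len(ncol(cmb))) {
        sa <- pa$sample[pa$location %in% cmb[, k]]
        sh <- shared_in(sa)
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          patient = p, loc_a = cmb[1, k], loc_b = cmb[2, k],
          shared = sh, additional = sh - p_shared, stringsAsFactors = FALSE)
      }
    }
    for (l in locs) {
      s_here <- pa$sample[pa$location == l]
      s_other <- pa$sample[pa$location != l]
      here <- presence[, s_here]
      total <- as.integer(sum(here))
      uniq <- if (length(s_other) > 0) {
        as.integer(sum(here & rowSums(presence[, s_other, drop = FALSE]) == 0))
      } else NA_integer_
      loc_rows[[length(loc_rows) + 1L]] <- data.frame(
        patient = p, location = l, unique_count = uniq, location_total = total,
        stringsAsFactors = FALSE)
    }
  }

  structure(list(global_shared = global_shared, subtypes = sub_df,
                 patients = pat_df,
                 pairs = if (length(pair_rows)) do.call(rbind, pair_rows) else
                   data.frame(patient = character(), loc_a = character(),
                              loc_b = character(), shared = numeric(),
                              additional = numeric()),
                 locations = do.call(rbind, loc_rows)),
            class = "slice_decomposition")
}

#' Partial multisite presence counts for one subtype
#'
#' For a subtype whose patients each have three sampled locations, counts
#' features present (i) in all locations of every patient, (ii) in at
#' least one location of every patient, and (iii) in at least one location
#' of every patient while in no patient present in all of that patient's
#' locations (the partial-multisite profile). The simple difference
#' (ii) - (i) is returned alongside as `at_least_one_minus_all`.
#'
#' @param presence A `presence_matrix`.
#' @param annotation A [sample_annotation()].
#' @param subtype Subtype to analyse.
#' @return A list with `all_locations`, `at_least_one`, `one_or_two_only`,
#'   `at_least_one_minus_all`.
#' @export
partial_multisite_counts <- function(presence, annotation, subtype) {
  ann <- annotation[annotation$subtype == subtype, , drop = FALSE]
  if (nrow(ann) == 0) stop("no samples for subtype '", subtype, "'")
  patients <- unique(ann$patient)
  in_all <- rep(TRUE, nrow(presence))   # all locations of every patient
  in_any <- rep(TRUE, nrow(presence))   # >=1 location of every patient
  full_somewhere <- rep(FALSE, nrow(presence))  # all locations of >=1 patient
  for (p in patients) {
    s <- ann$sample[ann$patient == p]
    rs <- rowSums(presence[, s, drop = FALSE])
    in_all <- in_all & rs == length(s)
    in_any <- in_any & rs >= 1
    full_somewhere <- full_somewhere | rs == length(s)
  }
  list(all_locations = sum(in_all),
       at_least_one = sum(in_any),
       one_or_two_only = sum(in_any & !full_somewhere),
       at_least_one_minus_all = sum(in_any) - sum(in_all))
}

#' Subtype marker features
#'
#' Features present in at least one location of every patient of
#' `subtype_a` and absent from all samples of `subtype_b`. When
#' `subtype_b` is `NULL`, the feature must be absent from all samples of
#' every other (non-noise) subtype.
#'
#' @param presence A `presence_matrix`.
#' @param annotation A [sample_annotation()].
#' @param subtype_a Marker subtype.
#' @param subtype_b Excluded subtype, or `NULL` for all others.
#' @return Sorted character vector of feature ids.
#' @export
subtype_markers <- function(presence, annotation, subtype_a, subtype_b = NULL) {
  ann_a <- annotation[annotation$subtype == subtype_a, , drop = FALSE]
  if (nrow(ann_a) == 0) stop("no samples for subtype '", subtype_a, "'")
  keep <- rep(TRUE, nrow(presence))
  for (p in unique(ann_a$patient)) {
    s <- ann_a$sample[ann_a$patient == p]
    keep <- keep & rowSums(presence[, s, drop = FALSE]) >= 1
  }
  others <- if (is.null(subtype_b)) {
    setdiff(unique(annotation$subtype), c(subtype_a, "noise_control"))
  } else subtype_b
  for (s_other in others) {
    so <- annotation$sample[annotation$subtype == s_other]
    if (length(so) == 0) stop("no samples for subtype '", s_other, "'")
    keep <- keep & rowSums(presence[, so, drop = FALSE]) == 0
  }
  sort(rownames(presence)[keep])
}

#' Expected number of location-unique features under a random null
#'
#' Null model: each feature keeps its number of occurrences `k` but is
#' re-placed uniformly at random among all `N` samples. Reports the
#' Monte-Carlo mean and SD over permutations of the per-location count of
#' within-patient-unique features (averaged over locations), together with
#' the closed form `sum_f C(N - m, k_f - 1) / C(N, k_f)` per location
#' (`m` = locations of that patient).
#'
#' @param presence A `presence_matrix`.
#' @param annotation A [sample_annotation()].
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer RNG seed.
#' @return A list with `expectation` (Monte-Carlo mean per location),
#'   `permutation_sd`, and `closed_form` (data frame per patient/location).
#' @export
expected_unique_per_location <- function(presence, annotation, n_perm = 1000,
                                         seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  ann <- annotation[annotation$subtype != "noise_control", , drop = FALSE]
  ann <- ann[match(colnames(presence), ann$sample), , drop = FALSE]
  N <- nrow(ann)
  k <- rowSums(presence)
  if (any(k > N)) stop("feature occurs in more samples than exist")
  k <- k[k > 0]

  # closed form per location: feature lands in L and misses the patient's
  # other m-1 locations
  cf_rows <- list()
  for (p in unique(ann$patient)) {
    m <- sum(ann$patient == p)
    ev <- sum(exp(lchoose(N - m, k - 1) - lchoose(N, k)))
    for (l in ann$location[ann$patient == p]) {
      cf_rows[[length(cf_rows) + 1L]] <- data.frame(
        patient = p, location = l, expected_unique = ev,
        stringsAsFactors = FALSE)
    }
  }
  closed_form <- do.call(rbind, cf_rows)

  set.seed(as.integer(seed))
  patient_of <- ann$patient
  per_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- matrix(FALSE, length(k), N)
    for (f in seq_along(k)) {
      perm[f, sample.int(N, k[f])] <- TRUE
    }
    uniq_per_loc <- numeric(N)
    for (j in seq_len(N)) {
      others <- which(patient_of == patient_of[j])
      others <- setdiff(others, j)
      uniq_per_loc[j] <- sum(perm[, j] &
                               rowSums(perm[, others, drop = FALSE]) == 0)
    }
    per_perm[b] <- mean(uniq_per_loc)
  }
  list(expectation = mean(per_perm),
       permutation_sd = stats::sd(per_perm),
       closed_form = closed_form)
}

#' Flatten a slice decomposition into a per-patient table
#'
#' One row per patient with the cumulative and additional slice sizes at
#' every level, per-pair shared counts, and per-location unique counts,
#' totals and percent-unique.
#'
#' @param decomposition A `slice_decomposition` (see [decompose_presence()]).
#' @return A data frame, one row per patient.
#' @export
venn_tables <- function(decomposition) {
  d <- decomposition
  rows <- list()
  for (i in seq_len(nrow(d$patients))) {
    p <- d$patients$patient[i]
    row <- data.frame(patient = p, subtype = d$patients$subtype[i],
                      global_shared = d$global_shared,
                      subtype_shared = d$subtypes$shared[
                        d$subtypes$subtype == d$patients$subtype[i]],
                      subtype_additional = d$subtypes$additional[
                        d$subtypes$subtype == d$patients$subtype[i]],
                      patient_shared = d$patients$shared[i],
                      patient_additional = d$patients$additional[i],
                      stringsAsFactors = FALSE)
    pp <- d$pairs[d$pairs$patient == p, , drop = FALSE]
    for (j in seq_len(nrow(pp))) {
      tag <- paste0("pair_", pp$loc_a[j], "_", pp$loc_b[j])
      row[[paste0(tag, "_shared")]] <- pp$shared[j]
      row[[paste0(tag, "_additional")]] <- pp$additional[j]
    }
    ll <- d$locations[d$locations$patient == p, , drop = FALSE]
    for (j in seq_len(nrow(ll))) {
      l <- ll$location[j]
      row[[paste0("unique_", l)]] <- ll$unique_count[j]
      row[[paste0("total_", l)]] <- ll$location_total[j]
      row[[paste0("pct_unique_", l)]] <-
        if (!is.na(ll$unique_count[j]) && ll$location_total[j] > 0)
          100 * ll$unique_count[j] / ll$location_total[j] else NA_real_
    }
    rows[[length(rows) + 1L]] <- row
  }
  nm <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) { r[setdiff(nm, names(r))] <- NA; r[nm] })
  do.call(rbind, rows)
}

#' Write Venn slice tables to TSV and JSON
#' @param decomposition A `slice_decomposition`.
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_venn_tables <- function(decomposition, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tbl <- venn_tables(decomposition)
  tsv <- file.path(dir, "venn_slices.tsv")
  utils::write.table(tbl, tsv, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  js <- file.path(dir, "venn_slices.json")
  jsonlite::write_json(
    list(global_shared = decomposition$global_shared,
         subtypes = decomposition$subtypes,
         patients = decomposition$patients,
         pairs = decomposition$pairs,
         locations = decomposition$locations),
    js, auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null")
  invisible(c(tsv, js))
}
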