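test_that("presence calling treats zero and missing as absent", {
  m <- matrix(c(1.5, 0, NA, 2), 2,
              dimnames = list(c("f1", "f2"), c("s1", "s2")))
  pres <- call_presence(expression_matrix(m, "lfq_intensity"))
  expect_identical(unclass(pres)[, "s1"], c(f1 = TRUE, f2 = FALSE))
  expect_identical(unclass(pres)[, "s2"], c(f1 = FALSE, f2 = TRUE))
  all_pos <- expression_matrix(matrix(1, 2, 2, dimnames = dimnames(m)), "cpm")
  expect_true(all(call_presence(all_pos)))
  counts <- expression_matrix(matrix(1L, 2, 2, dimnames = dimnames(m)), "raw_counts")
  expect_error(call_presence(counts), "lfq_intensity or cpm")
})

test_that("decomposition agrees with the membership-pattern oracle on random matrices", {
  ann <- small_annotation()
  for (seed in 1:4) {
    pres <- random_presence(ann, n_features = 120, p = 0.75, seed = seed)
    dec <- decompose_presence(pres, ann)
    ora <- oracle_decompose(pres, ann)
    expect_identical(dec$global_shared, ora$global)
    expect_equal(setNames(dec$subtypes$shared, dec$subtypes$subtype),
                 ora$subtype[dec$subtypes$subtype])
    expect_equal(setNames(dec$patients$shared, dec$patients$patient),
                 ora$patient[dec$patients$patient])
    got_pairs <- setNames(dec$pairs$shared,
                          paste(dec$pairs$patient, dec$pairs$loc_a, dec$pairs$loc_b))
    expect_equal(got_pairs, ora$pairs[names(got_pairs)])
    got_uni <- setNames(dec$locations$unique_count,
                        paste(dec$locations$patient, dec$locations$location))
    expect_equal(got_uni, ora$unique[names(got_uni)])
  }
})

test_that("slice decomposition satisfies its additivity invariants", {
  ann <- small_annotation()
  pres <- random_presence(ann, n_features = 150, p = 0.8, seed = 7)
  dec <- decompose_presence(pres, ann)
  expect_equal(dec$subtypes$shared, dec$global_shared + dec$subtypes$additional)
  sub_shared <- setNames(dec$subtypes$shared, dec$subtypes$subtype)
  expect_equal(dec$patients$shared,
               unname(sub_shared[dec$patients$subtype]) + dec$patients$additional)
  expect_true(all(dec$pairs$additional >= 0))
  expect_true(all(dec$locations$unique_count <= dec$locations$location_total))
  # unique(L) + sum of pairwise additionals touching L + patient_shared = total(L)
  for (i in seq_len(nrow(dec$locations))) {
    p <- dec$locations$patient[i]; l <- dec$locations$location[i]
    pp <- dec$pairs[dec$pairs$patient == p &
                      (dec$pairs$loc_a == l | dec$pairs$loc_b == l), ]
    ps <- dec$patients$shared[dec$patients$patient == p]
    expect_identical(dec$locations$unique_count[i] + sum(pp$additional) + ps,
                     dec$locations$location_total[i])
  }
})

test_that("all-present matrix puts everything into the global slice", {
  ann <- small_annotation()
  pres <- random_presence(ann, n_features = 40, p = 1.1, seed = 1)  # all TRUE
  dec <- decompose_presence(pres, ann)
  expect_identical(dec$global_shared, 40L)
  expect_true(all(dec$subtypes$additional == 0))
  expect_true(all(dec$patients$additional == 0))
  expect_true(all(dec$locations$unique_count == 0))
})

test_that("partial multisite counts match hand enumeration on a toy case", {
  ann <- sample_annotation(data.frame(
    sample = sprintf("P%d_L%d", rep(1:2, each = 3), rep(1:3, 2)),
    patient = sprintf("P%d", rep(1:2, each = 3)),
    subtype = "infiltrative",
    location = sprintf("L%d", rep(1:3, 2)), stringsAsFactors = FALSE))
  # rows: feature presence per sample (P1_L1..L3, P2_L1..L3)
  pres <- rbind(
    everywhere    = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    two_locs_each = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
    full_p1_two_p2 = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    one_loc_each  = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
    missing_p2    = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    absent        = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  colnames(pres) <- ann$sample
  res <- partial_multisite_counts(pres, ann, "infiltrative")
  expect_identical(res$all_locations, 1L)        # everywhere
  expect_identical(res$at_least_one, 4L)         # all but missing_p2, absent
  # in every patient but in no patient complete: two_locs_each, one_loc_each
  expect_identical(res$one_or_two_only, 2L)
  expect_identical(res$at_least_one_minus_all, 3L)
})

test_that("subtype markers follow the presence/absence definitions", {
  ann <- cohort_annotation(3, 2, 2)  # 3 subtypes x 2 patients x 2 locations
  n <- nrow(ann)
  pres <- matrix(TRUE, 3, n, dimnames = list(c("ubiq", "m1", "m2"), ann$sample))
  # m1, m2: present in >=1 location of every nodular patient, absent elsewhere
  for (f in c("m1", "m2")) {
    pres[f, ] <- FALSE
    for (p in unique(ann$patient[ann$subtype == "nodular"])) {
      pres[f, ann$sample[ann$patient == p][1]] <- TRUE
    }
  }
  class(pres) <- c("presence_matrix", class(pres))
  expect_identical(subtype_markers(pres, ann, "nodular"), c("m1", "m2"))
  expect_identical(subtype_markers(pres, ann, "nodular", "infiltrative"),
                   c("m1", "m2"))
  # a feature present in all samples is not a marker for any pair
  expect_false("ubiq" %in% subtype_markers(pres, ann, "infiltrative", "nodular"))
  # antisymmetry: markers(A not B) and markers(B not A) are disjoint
  for (seed in 1:3) {
    rp <- random_presence(ann, 60, p = 0.5, seed = seed)
    a <- subtype_markers(rp, ann, "infiltrative", "superficial")
    b <- subtype_markers(rp, ann, "superficial", "infiltrative")
    expect_length(intersect(a, b), 0)
  }
})

test_that("expected unique-per-location matches its closed form", {
  # one patient, three samples, every feature in exactly one sample:
  # closed form per location = n_features / 3
  ann <- sample_annotation(data.frame(
    sample = c("s1", "s2", "s3"), patient = "P1", subtype = "nodular",
    location = c("L1", "L2", "L3"), stringsAsFactors = FALSE))
  m <- matrix(FALSE, 9, 3, dimnames = list(sprintf("F%d", 1:9), ann$sample))
  for (i in 1:9) m[i, (i %% 3) + 1] <- TRUE
  res <- expected_unique_per_location(m, ann, n_perm = 100, seed = 2)
  expect_equal(unique(res$closed_form$expected_unique), 3)

  # every feature everywhere -> expectation 0
  full <- matrix(TRUE, 5, 3, dimnames = list(sprintf("F%d", 1:5), ann$sample))
  res0 <- expected_unique_per_location(full, ann, n_perm = 20, seed = 1)
  expect_equal(res0$expectation, 0)
  expect_equal(unique(res0$closed_form$expected_unique), 0)

  # permutation estimate converges to the closed form (multi-patient case)
  ann2 <- small_annotation()
  pres <- random_presence(ann2, n_features = 60, p = 0.5, seed = 3)
  res2 <- expected_unique_per_location(pres, ann2, n_perm = 1000, seed = 4)
  cf <- mean(res2$closed_form$expected_unique)
  se <- res2$permutation_sd / sqrt(1000)
  expect_lt(abs(res2$expectation - cf), 3 * se + 1e-9)
})

test_that("venn tables flatten the decomposition consistently and round-trip", {
  ref <- proteome_venn_reference()
  pres <- build_presence_fixture(ref$spec, ref$annotation)
  dec <- decompose_presence(pres, ref$annotation)
  tbl <- venn_tables(dec)
  p1 <- tbl[tbl$patient == "P1", ]
  expect_equal(p1$subtype_shared, p1$global_shared + p1$subtype_additional)
  expect_equal(p1$patient_shared, p1$subtype_shared + p1$patient_additional)
  expect_equal(p1$pair_L1_L2_shared, p1$patient_shared + p1$pair_L1_L2_additional)
  expect_equal(p1$pct_unique_L1, 100 * 85 / 3656)

  dir <- withr::local_tempdir()
  paths <- write_venn_tables(dec, dir)
  js <- jsonlite::read_json(file.path(dir, "venn_slices.json"),
                            simplifyVector = TRUE)
  expect_equal(js$global_shared, dec$global_shared)
  expect_equal(js$patients$shared, dec$patients$shared)

  # empty matrix -> all-zero slices
  empty <- random_presence(ref$annotation, 5, p = -1, seed = 1)  # all FALSE
  dec0 <- decompose_presence(empty, ref$annotation)
  tbl0 <- venn_tables(dec0)
  expect_true(all(tbl0$patient_shared == 0))
  expect_true(all(tbl0[, grepl("^unique_", names(tbl0))] == 0))
})
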