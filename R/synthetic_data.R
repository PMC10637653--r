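# Synthetic cohorts emulating the multisite BCC design: 3 histological
# subtypes x 3 patients x 3 sampled locations per lesion, with a
# hierarchical block-covariance expression model, presence/absence fixtures
# with prescribed intersection cardinalities, negative-binomial RNA counts
# with injected heterogeneous genes, and multinomial allele pileups with
# injected divergent positions.

#' Configuration for the hierarchical expression generator
#'
#' Log-scale expression is modeled as a sum of independent Gaussian effects:
#' a global per-feature mean (SD `sigma_global`), plus subtype-, patient-
#' and location-level effects and measurement noise. Because samples of the
#' same patient share more effect terms than samples of different patients,
#' the generated cohort reproduces the empirical ordering of correlation
#' groups: noise replicates > intra-patient > intra-subtype > inter-subtype.
#'
#' @param n_subtypes Number of subtypes (at most 3: infiltrative,
#'   superficial, nodular).
#' @param patients_per_subtype Patients per subtype.
#' @param locations_per_patient Sampled locations per lesion.
#' @param n_features Number of features (proteins/genes).
#' @param sigma_global SD of the per-feature global log mean; drives the
#'   baseline similarity of all profiles.
#' @param sigma_subtype,sigma_patient,sigma_location,sigma_noise SDs of the
#'   nested log-scale effects, from coarsest to finest.
#' @param presence_dropout Named probabilities `subtype`, `patient`,
#'   `location` that a feature is unobserved for that whole level.
#' @param base_log_mean Log-scale grand mean of intensities.
#' @param seed Integer RNG seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subtypes = 3, patients_per_subtype = 3,
                          locations_per_patient = 3, n_features = 1500,
                          sigma_global = 1.5, sigma_subtype = 0.4,
                          sigma_patient = 0.4, sigma_location = 0.25,
                          sigma_noise = 0.05,
                          presence_dropout = c(subtype = 0.02, patient = 0.03,
                                               location = 0.05),
                          base_log_mean = 14, seed = 1) {
  if (n_subtypes < 1 || n_subtypes > 3) stop("n_subtypes must be in 1..3")
  sds <- c(sigma_global, sigma_subtype, sigma_patient, sigma_location, sigma_noise)
  if (any(sds < 0)) stop("all effect SDs must be >= 0")
  pd <- presence_dropout[c("subtype", "patient", "location")]
  if (any(is.na(pd)) || any(pd < 0) || any(pd > 1)) {
    stop("presence_dropout must give probabilities in [0,1] for subtype, patient, location")
  }
  structure(list(n_subtypes = n_subtypes,
                 patients_per_subtype = patients_per_subtype,
                 locations_per_patient = locations_per_patient,
                 n_features = n_features,
                 sigma_global = sigma_global, sigma_subtype = sigma_subtype,
                 sigma_patient = sigma_patient, sigma_location = sigma_location,
                 sigma_noise = sigma_noise, presence_dropout = pd,
                 base_log_mean = base_log_mean, seed = as.integer(seed)),
            class = "cohort_config")
}

# Deterministic cohort annotation: patients numbered across subtypes,
# sample ids "P<i>_L<j>".
cohort_annotation <- function(n_subtypes = 3, patients_per_subtype = 3,
                              locations_per_patient = 3) {
  subtypes <- c("infiltrative", "superficial", "nodular")[seq_len(n_subtypes)]
  rows <- list()
  pat <- 0L
  for (s in subtypes) {
    for (i in seq_len(patients_per_subtype)) {
      pat <- pat + 1L
      for (l in seq_len(locations_per_patient)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sprintf("P%d_L%d", pat, l), patient = sprintf("P%d", pat),
          subtype = s, location = sprintf("L%d", l), stringsAsFactors = FALSE)
      }
    }
  }
  sample_annotation(do.call(rbind, rows))
}

#' Generate a hierarchical multisite expression matrix
#'
#' Draws log-scale intensities from the nested Gaussian model described in
#' [cohort_config()], exponentiates, and applies hierarchical presence
#' dropout (a feature may be unobserved for a whole subtype, a whole
#' patient, or a single location; unobserved cells are `NA`).
#'
#' @param config A [cohort_config()].
#' @return A list with elements `matrix` (an [expression_matrix()] of kind
#'   `lfq_intensity`) and `annotation` (a [sample_annotation()]).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  ann <- cohort_annotation(config$n_subtypes, config$patients_per_subtype,
                           config$locations_per_patient)
  nf <- config$n_features
  ns <- nrow(ann)
  set.seed(config$seed)
  mu <- stats::rnorm(nf, config$base_log_mean, config$sigma_global)

  subtypes <- unique(ann$subtype)
  patients <- unique(ann$patient)
  eff_subtype <- matrix(stats::rnorm(nf * length(subtypes), 0, config$sigma_subtype),
                        nf, length(subtypes), dimnames = list(NULL, subtypes))
  eff_patient <- matrix(stats::rnorm(nf * length(patients), 0, config$sigma_patient),
                        nf, length(patients), dimnames = list(NULL, patients))
  logval <- mu +
    eff_subtype[, ann$subtype, drop = FALSE] +
    eff_patient[, ann$patient, drop = FALSE] +
    matrix(stats::rnorm(nf * ns, 0, config$sigma_location), nf, ns) +
    matrix(stats::rnorm(nf * ns, 0, config$sigma_noise), nf, ns)
  vals <- exp(logval)

  # hierarchical dropout: whole-subtype, whole-patient, single-location
  pd <- config$presence_dropout
  drop_sub <- matrix(stats::runif(nf * length(subtypes)) < pd[["subtype"]],
                     nf, length(subtypes), dimnames = list(NULL, subtypes))
  drop_pat <- matrix(stats::runif(nf * length(patients)) < pd[["patient"]],
                     nf, length(patients), dimnames = list(NULL, patients))
  drop_loc <- matrix(stats::runif(nf * ns) < pd[["location"]], nf, ns)
  absent <- drop_sub[, ann$subtype, drop = FALSE] |
    drop_pat[, ann$patient, drop = FALSE] | drop_loc
  vals[absent] <- NA_real_

  rownames(vals) <- sprintf("F%05d", seq_len(nf))
  colnames(vals) <- ann$sample
  list(matrix = expression_matrix(vals, "lfq_intensity"), annotation = ann)
}

#' Generate technical noise replicates of one profile
#'
#' Emulates a noise-control group of repeated LC-MS measurements of the
#' same sample: each replicate is the base profile times small
#' multiplicative lognormal noise.
#'
#' @param base_sample Named nonnegative numeric vector (one profile); `NA`
#'   means unobserved and stays `NA` in every replicate.
#' @param n_reps Number of replicates (>= 2).
#' @param sigma_noise Log-scale noise SD.
#' @param seed Integer RNG seed.
#' @return An [expression_matrix()] of kind `lfq_intensity` with columns
#'   `NOISE_R1..NOISE_Rn`.
#' @export
generate_noise_replicates <- function(base_sample, n_reps = 5,
                                      sigma_noise = 0.05, seed = 1) {
  if (n_reps < 2) stop("n_reps must be >= 2")
  if (is.null(names(base_sample))) stop("base_sample must be a named vector")
  set.seed(as.integer(seed))
  nf <- length(base_sample)
  noise <- matrix(exp(stats::rnorm(nf * n_reps, 0, sigma_noise)), nf, n_reps)
  vals <- base_sample * noise
  rownames(vals) <- names(base_sample)
  colnames(vals) <- sprintf("NOISE_R%d", seq_len(n_reps))
  expression_matrix(vals, "lfq_intensity")
}

#' Annotation rows for a noise-replicate matrix
#' @param noise An expression matrix produced by [generate_noise_replicates()].
#' @return A [sample_annotation()] with subtype `noise_control`.
#' @export
noise_annotation <- function(noise) {
  sample_annotation(data.frame(sample = colnames(noise), patient = "NOISE",
                               subtype = "noise_control", location = "",
                               stringsAsFactors = FALSE))
}

#' Specify additive Venn-slice sizes for a presence fixture
#'
#' Describes how many features fall into each membership pattern of the
#' nested intersection hierarchy: shared by all samples, additionally
#' shared by all samples of one subtype, additionally by all locations of
#' one patient, additionally by one location pair of a patient, or unique
#' to a single location. Optional `location_total` rows are checked at
#' build time: global + subtype + patient + pairs-containing-L + unique(L)
#' must equal total(L).
#'
#' @param global_shared Features present in every sample.
#' @param subtype_additional Named integer vector (names = subtypes).
#' @param patient_additional Named integer vector (names = patient ids).
#' @param pairwise_additional Data frame `patient`, `loc_a`, `loc_b`, `count`.
#' @param location_unique Data frame `patient`, `location`, `count`.
#' @param location_total Optional data frame `patient`, `location`, `total`
#'   used for consistency checking.
#' @return A list of class `slice_spec`.
#' @export
slice_spec <- function(global_shared = 0L, subtype_additional = integer(),
                       patient_additional = integer(),
                       pairwise_additional = NULL, location_unique = NULL,
                       location_total = NULL) {
  empty_pair <- data.frame(patient = character(), loc_a = character(),
                           loc_b = character(), count = integer(),
                           stringsAsFactors = FALSE)
  empty_uni <- data.frame(patient = character(), location = character(),
                          count = integer(), stringsAsFactors = FALSE)
  spec <- list(global_shared = as.integer(global_shared),
               subtype_additional = subtype_additional,
               patient_additional = patient_additional,
               pairwise_additional = if (is.null(pairwise_additional)) empty_pair else pairwise_additional,
               location_unique = if (is.null(location_unique)) empty_uni else location_unique,
               location_total = location_total)
  counts <- c(spec$global_shared, spec$subtype_additional,
              spec$patient_additional, spec$pairwise_additional$count,
              spec$location_unique$count)
  if (any(counts < 0)) stop("slice sizes must be nonnegative")
  class(spec) <- "slice_spec"
  spec
}

#' Build a presence/absence fixture realizing prescribed slice sizes
#'
#' Assigns features to membership patterns deterministically (in feature-id
#' order: global block first, then subtype, patient, location-pair and
#' single-location blocks) so that every slice cardinality of the spec is
#' realized exactly by [decompose_presence()].
#'
#' @param spec A [slice_spec()].
#' @param annotation A [sample_annotation()] (noise-control rows ignored).
#' @return A logical feature x sample matrix of class `presence_matrix`.
#' @export
build_presence_fixture <- function(spec, annotation) {
  stopifnot(inherits(spec, "slice_spec"))
  ann <- annotation[annotation$subtype != "noise_control", , drop = FALSE]
  samples <- ann$sample
  subtype_of <- function(p) unique(ann$subtype[ann$patient == p])

  # consistency: per-location totals must close
  if (!is.null(spec$location_total)) {
    for (i in seq_len(nrow(spec$location_total))) {
      p <- spec$location_total$patient[i]
      l <- spec$location_total$location[i]
      tot <- spec$location_total$total[i]
      pa <- spec$pairwise_additional
      pair_sum <- sum(pa$count[pa$patient == p & (pa$loc_a == l | pa$loc_b == l)])
      uni <- spec$location_unique
      uni_sum <- sum(uni$count[uni$patient == p & uni$location == l])
      sub_add <- if (length(spec$subtype_additional)) {
        s <- subtype_of(p)
        if (s %in% names(spec$subtype_additional)) spec$subtype_additional[[s]] else 0L
      } else 0L
      pat_add <- if (p %in% names(spec$patient_additional)) spec$patient_additional[[p]] else 0L
      got <- spec$global_shared + sub_add + pat_add + pair_sum + uni_sum
      if (got != tot) {
        stop(sprintf(
          "inconsistent slice spec: patient %s location %s sums to %d, total says %d",
          p, l, got, tot))
      }
    }
  }

  blocks <- list()
  add_block <- function(n, members) {
    if (n > 0) blocks[[length(blocks) + 1L]] <<- list(n = n, members = members)
  }
  add_block(spec$global_shared, samples)
  for (s in names(spec$subtype_additional)) {
    add_block(spec$subtype_additional[[s]], ann$sample[ann$subtype == s])
  }
  for (p in names(spec$patient_additional)) {
    add_block(spec$patient_additional[[p]], ann$sample[ann$patient == p])
  }
  pa <- spec$pairwise_additional
  for (i in seq_len(nrow(pa))) {
    memb <- ann$sample[ann$patient == pa$patient[i] &
                         ann$location %in% c(pa$loc_a[i], pa$loc_b[i])]
    add_block(pa$count[i], memb)
  }
  uni <- spec$location_unique
  for (i in seq_len(nrow(uni))) {
    memb <- ann$sample[ann$patient == uni$patient[i] &
                         ann$location == uni$location[i]]
    add_block(uni$count[i], memb)
  }

  n_total <- sum(vapply(blocks, function(b) b$n, numeric(1)))
  pres <- matrix(FALSE, n_total, length(samples),
                 dimnames = list(sprintf("F%05d", seq_len(n_total)), samples))
  at <- 0L
  for (b in blocks) {
    pres[at + seq_len(b$n), b$members] <- TRUE
    at <- at + b$n
  }
  structure(pres, class = c("presence_matrix", class(pres)))
}

#' Published proteome intersection table as a fixture specification
#'
#' The per-patient Venn-slice sizes reported for the 27-sample BCC proteome
#' (9 patients, 3 subtypes, 3 locations): 1760 proteins shared by all
#' samples; +749 shared by all infiltrative samples (2509 total; 2099
#' superficial, 2504 nodular); Patient 1 adds 691 (3200 shared across its
#' locations), its L1/L2 pair adds 118 (3318), Location 1 carries 85 unique
#' proteins and 3656 proteins in total, which closes the unprinted L1/L3
#' pair slice at 253.
#'
#' @return A list with elements `spec` (a [slice_spec()]) and `annotation`
#'   (the 27-sample [sample_annotation()]).
#' @export
proteome_venn_reference <- function() {
  ann <- cohort_annotation(3, 3, 3)
  spec <- slice_spec(
    global_shared = 1760L,
    subtype_additional = c(infiltrative = 749L, superficial = 339L, nodular = 744L),
    patient_additional = c(P1 = 691L),
    pairwise_additional = data.frame(
      patient = c("P1", "P1"), loc_a = c("L1", "L1"), loc_b = c("L2", "L3"),
      count = c(118L, 253L), stringsAsFactors = FALSE),
    location_unique = data.frame(patient = "P1", location = "L1", count = 85L,
                                 stringsAsFactors = FALSE),
    location_total = data.frame(patient = "P1", location = "L1", total = 3656L,
                                stringsAsFactors = FALSE))
  list(spec = spec, annotation = ann)
}

#' Published transcriptome intersection table as a fixture specification
#'
#' The per-patient Venn-slice sizes reported for the 9-sample BCC
#' transcriptome (3 patients, one per subtype, 3 locations): 20,099 genes
#' shared by all samples; the infiltrative patient adds 6,877 (26,976
#' shared across its locations), its L1/L2 pair adds 2,137 (29,113),
#' Location 1 carries 368 unique genes and 29,905 genes in total, closing
#' the unprinted L1/L3 slice at 424.
#'
#' @return A list with elements `spec` and `annotation` (9 samples).
#' @export
transcriptome_venn_reference <- function() {
  ann <- cohort_annotation(3, 1, 3)
  spec <- slice_spec(
    global_shared = 20099L,
    patient_additional = c(P1 = 6877L),
    pairwise_additional = data.frame(
      patient = c("P1", "P1"), loc_a = c("L1", "L1"), loc_b = c("L2", "L3"),
      count = c(2137L, 424L), stringsAsFactors = FALSE),
    location_unique = data.frame(patient = "P1", location = "L1", count = 368L,
                                 stringsAsFactors = FALSE),
    location_total = data.frame(patient = "P1", location = "L1", total = 29905L,
                                stringsAsFactors = FALSE))
  list(spec = spec, annotation = ann)
}

#' Configuration for the RNA count generator
#'
#' @param n_genes Number of genes.
#' @param n_patients Patients (one subtype each, up to 3).
#' @param locations_per_patient Locations per patient.
#' @param mean_count Mean sequencing depth per gene (gene means are drawn
#'   lognormally around it).
#' @param dispersion Negative-binomial dispersion (variance = mu + mu^2 * dispersion).
#' @param n_het_genes Genes injected with a location-specific fold change.
#' @param fc Injected fold change (linear scale).
#' @param patients_affected Number of patients in which each injected gene
#'   is perturbed.
#' @param seed Integer RNG seed.
#' @return A list of class `count_sim_config`.
#' @export
count_sim_config <- function(n_genes = 200, n_patients = 3,
                             locations_per_patient = 3, mean_count = 500,
                             dispersion = 0.1, n_het_genes = 20, fc = 8,
                             patients_affected = 2, seed = 1) {
  if (patients_affected > n_patients) stop("patients_affected > n_patients")
  if (n_het_genes > n_genes) stop("n_het_genes > n_genes")
  structure(as.list(environment()), class = "count_sim_config")
}

#' Generate negative-binomial RNA counts with injected heterogeneous genes
#'
#' A configurable subset of genes receives a location-specific fold change
#' of size `fc` in `patients_affected` patients (one perturbed location per
#' affected patient); all counts are negative binomial around lognormal
#' gene means. The identities of the injected genes are returned for
#' recovery testing.
#'
#' @param config A [count_sim_config()].
#' @return A list with `counts` (kind `raw_counts`), `annotation`, and
#'   `truth` (character vector of injected gene ids).
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "count_sim_config"))
  ann <- cohort_annotation(config$n_patients, 1, config$locations_per_patient)
  ns <- nrow(ann)
  ng <- config$n_genes
  set.seed(config$seed)
  gene_mu <- stats::rlnorm(ng, log(config$mean_count), 0.7)
  mu <- matrix(gene_mu, ng, ns)
  rownames(mu) <- sprintf("G%05d", seq_len(ng))
  colnames(mu) <- ann$sample

  truth <- character(0)
  if (config$n_het_genes > 0) {
    het <- sort(sample.int(ng, config$n_het_genes))
    truth <- rownames(mu)[het]
    patients <- unique(ann$patient)
    for (g in het) {
      aff <- sample(patients, config$patients_affected)
      for (p in aff) {
        cols <- which(ann$patient == p)
        pick <- cols[sample.int(length(cols), 1L)]
        mu[g, pick] <- mu[g, pick] * config$fc
      }
    }
  }
  counts <- matrix(stats::rnbinom(ng * ns, mu = mu, size = 1 / config$dispersion),
                   ng, ns, dimnames = dimnames(mu))
  list(counts = expression_matrix(counts, "raw_counts"), annotation = ann,
       truth = truth)
}

#' Configuration for the allele-count generator
#'
#' @param n_positions Genome positions simulated (chrom `"chr1"`, positions
#'   spaced 1000 bp apart).
#' @param n_divergent Positions injected with an intra-patient allele-
#'   frequency divergence.
#' @param coverage Reads per sample per position.
#' @param n_patients,locations_per_patient Cohort shape.
#' @param het_fraction Fraction of null positions that are heterozygous
#'   (0.5/0.5) rather than homozygous.
#' @param divergent_split Reference/alternate frequency vector used at
#'   divergent positions in the perturbed locations (the first location
#'   keeps the pure reference allele).
#' @param seed Integer RNG seed.
#' @return A list of class `allele_sim_config`.
#' @export
allele_sim_config <- function(n_positions = 60, n_divergent = 6,
                              coverage = 500, n_patients = 3,
                              locations_per_patient = 3, het_fraction = 0.2,
                              divergent_split = c(0.4, 0.6), seed = 1) {
  if (n_divergent > n_positions) stop("n_divergent > n_positions")
  if (abs(sum(divergent_split) - 1) > 1e-9 || length(divergent_split) != 2) {
    stop("divergent_split must be two frequencies summing to 1")
  }
  structure(as.list(environment()), class = "allele_sim_config")
}

#' Generate multinomial allele counts with injected divergent positions
#'
#' Per position and patient a generating allele-frequency vector is drawn
#' (homozygous or heterozygous); every sample's base counts are multinomial
#' draws at the configured coverage. At injected positions the first
#' location keeps the pure reference allele while the remaining locations
#' of the same patient use the `divergent_split` reference/alternate mix,
#' so intra-patient pairs involving the first location diverge.
#'
#' @param config An [allele_sim_config()].
#' @return A list with `table` (an [allele_count_table()]), `annotation`,
#'   and `truth` (data frame of injected `chrom`, `pos`).
#' @export
generate_allele_counts <- function(config) {
  stopifnot(inherits(config, "allele_sim_config"))
  ann <- cohort_annotation(config$n_patients, 1, config$locations_per_patient)
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  pos <- 1000L * seq_len(config$n_positions)
  divergent <- sort(sample.int(config$n_positions, config$n_divergent))

  rows <- vector("list", config$n_positions * nrow(ann))
  k <- 0L
  for (i in seq_len(config$n_positions)) {
    for (p in unique(ann$patient)) {
      ref <- sample.int(4L, 1L)
      alt <- sample(setdiff(1:4, ref), 1L)
      base_freq <- numeric(4)
      if (stats::runif(1) < config$het_fraction) {
        base_freq[c(ref, alt)] <- 0.5
      } else {
        base_freq[ref] <- 1
      }
      samp <- ann[ann$patient == p, , drop = FALSE]
      for (j in seq_len(nrow(samp))) {
        freq <- base_freq
        if (i %in% divergent) {
          freq <- numeric(4)
          if (j == 1L) {
            freq[ref] <- 1
          } else {
            freq[ref] <- config$divergent_split[1]
            freq[alt] <- config$divergent_split[2]
          }
        }
        cnt <- as.integer(stats::rmultinom(1, config$coverage, freq))
        k <- k + 1L
        rows[[k]] <- data.frame(chrom = "chr1", pos = pos[i],
                                sample = samp$sample[j],
                                A = cnt[1], C = cnt[2], G = cnt[3], T = cnt[4],
                                stringsAsFactors = FALSE)
      }
    }
  }
  tbl <- allele_count_table(do.call(rbind, rows))
  list(table = tbl, annotation = ann,
       truth = data.frame(chrom = rep("chr1", length(divergent)),
                          pos = pos[divergent], stringsAsFactors = FALSE))
}
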