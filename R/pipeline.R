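# End-to-end orchestration: run the correlation, intersection, RNA
# heterogeneity and allelic heterogeneity stages from one configuration
# (user-supplied tables or synthetic generation), writing a report bundle
# plus a manifest of every output.

#' Read a flat key=value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment. Values are
#' parsed as numbers where possible. Keys use dots to express nesting
#' (e.g. `params.fc_threshold = 2`).
#'
#' @param path Path to the config file.
#' @return A nested list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    if (!is.na(num)) val <- num
    keys <- strsplit(key, ".", fixed = TRUE)[[1L]]
    if (length(keys) == 1L) {
      cfg[[keys]] <- val
    } else {
      if (is.null(cfg[[keys[1L]]])) cfg[[keys[1L]]] <- list()
      cfg[[keys[1L]]][[keys[2L]]] <- val
    }
  }
  cfg
}

#' Run the full heterogeneity pipeline
#'
#' Executes the stages applicable to the supplied data: correlation-group
#' analysis and intersection decomposition on the proteomics matrix, CPM /
#' fold-change heterogeneous-gene screening on the count matrix, and
#' Jensen-Shannon position calling on the allele table. Each modality is
#' either loaded from paths or generated synthetically; omitted modalities
#' are skipped and noted in the manifest. All randomness derives from one
#' root seed, split per stage.
#'
#' @param config Nested list (see [read_run_config()]) with optional
#'   blocks `proteomics` (`matrix` + `annotation` paths, or
#'   `synthetic = 1`), `rnaseq` (`counts` + `annotation`, or
#'   `synthetic = 1`), `snv` (`alleles` + `annotation`, or
#'   `synthetic = 1`), a `params` block (`bin_width`, `fc_threshold`,
#'   `min_patients`, `min_cov`, `js_threshold`, `n_perm`) and `seed`.
#' @param out_dir Output directory.
#' @return The manifest list, invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  prm <- config$params %||% list()
  p_get <- function(name, default) as.numeric(prm[[name]] %||% default)

  manifest <- list(seed = seed, parameters = prm, stages = list(),
                   outputs = character(0), skipped = character(0))
  t0 <- Sys.time()
  add_outputs <- function(paths) {
    manifest$outputs <<- c(manifest$outputs,
                           unname(vapply(paths, basename, character(1))))
  }
  stage_time <- function(name, start) {
    manifest$stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), start, units = "secs")))
  }

  # -- proteomics: correlations + intersections ------------------------------
  if (!is.null(config$proteomics)) {
    st <- Sys.time()
    pc <- config$proteomics
    if (!is.null(pc$matrix)) {
      mat <- read_expression_table(pc$matrix, "lfq_intensity")
      ann <- read_annotation(pc$annotation)
    } else {
      gen <- generate_expression(cohort_config(seed = seed))
      mat <- gen$matrix
      ann <- gen$annotation
    }
    pairs <- assign_groups(pairwise_correlations(mat, method = "both"), ann)
    rep_ <- heterogeneity_report(pairs, bin_width = p_get("bin_width", 0.01))
    add_outputs(write_heterogeneity_report(rep_, file.path(out_dir, "correlation")))
    pres <- call_presence(mat)
    dec <- decompose_presence(pres, ann)
    add_outputs(write_venn_tables(dec, file.path(out_dir, "venn")))
    emb <- pca_embedding(mat, n_components = min(3L, ncol(mat)))
    pca_path <- file.path(out_dir, "pca_coordinates.tsv")
    utils::write.table(data.frame(sample = rownames(emb$coordinates),
                                  emb$coordinates),
                       pca_path, sep = "\t", quote = FALSE, row.names = FALSE)
    add_outputs(pca_path)
    stage_time("proteomics", st)
  } else {
    manifest$skipped <- c(manifest$skipped, "proteomics")
  }

  # -- rnaseq: CPM + fold-change screening -----------------------------------
  if (!is.null(config$rnaseq)) {
    st <- Sys.time()
    rc <- config$rnaseq
    if (!is.null(rc$counts)) {
      counts <- read_expression_table(rc$counts, "raw_counts")
      ann_r <- read_annotation(rc$annotation)
    } else {
      gen <- generate_counts(count_sim_config(seed = seed + 1L))
      counts <- gen$counts
      ann_r <- gen$annotation
    }
    cpm <- filter_low_expression(cpm_normalize(counts))
    fc <- max_pairwise_fc(cpm, ann_r)
    sel <- select_heterogeneous(fc, fc_threshold = p_get("fc_threshold", 2),
                                min_patients = p_get("min_patients", 2))
    gene_path <- file.path(out_dir, "heterogeneous_genes.txt")
    if (any(sel$selected)) {
      add_outputs(export_gene_list(sel, gene_path))
      n_listed <- colSums(fc >= p_get("fc_threshold", 2))
      ov <- overlap_significance(as.integer(n_listed), nrow(fc),
                                 sum(sel$selected),
                                 n_perm = p_get("n_perm", 1000),
                                 seed = seed + 2L,
                                 min_patients = p_get("min_patients", 2))
      jp <- file.path(out_dir, "overlap_significance.json")
      jsonlite::write_json(ov, jp, auto_unbox = TRUE, digits = NA)
      add_outputs(jp)
    }
    stage_time("rnaseq", st)
  } else {
    manifest$skipped <- c(manifest$skipped, "rnaseq")
  }

  # -- snv: JS position calling ----------------------------------------------
  if (!is.null(config$snv)) {
    st <- Sys.time()
    sc <- config$snv
    if (!is.null(sc$alleles)) {
      tbl <- read_allele_counts(sc$alleles)
      ann_s <- read_annotation(sc$annotation)
    } else {
      gen <- generate_allele_counts(allele_sim_config(seed = seed + 3L))
      tbl <- gen$table
      ann_s <- gen$annotation
    }
    calls <- call_positions(tbl, ann_s, min_cov = p_get("min_cov", 10),
                            threshold = p_get("js_threshold", 0.6))
    cp <- file.path(out_dir, "position_calls.tsv")
    report_calls(calls, cp)
    add_outputs(cp)
    stage_time("snv", st)
  } else {
    manifest$skipped <- c(manifest$skipped, "snv")
  }

  manifest$total_seconds <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
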