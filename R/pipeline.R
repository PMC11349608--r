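#' Pipeline run configuration
#'
#' Bundles the knobs of a per-sample or cohort run. Paths are validated at
#' construction.
#'
#' @param ref A `trb_reference` (default the bundled one).
#' @param qc A [qc_params()] object.
#' @param min_score Minimum V/J alignment score (default 10).
#' @param region_edges Frequency-region breakpoints.
#' @param length_weighting `"by_clonotype"` or `"by_read"`.
#' @param alpha Raw-p significance threshold for comparisons.
#' @param out_dir Output directory (created on demand).
#' @return A list of class `run_config`.
#' @export
run_config <- function(ref = trb_reference(), qc = qc_params(),
                       min_score = 10L,
                       region_edges = c(0, 1e-5, 1e-4, 1e-3, 1e-2, 1),
                       length_weighting = "by_clonotype",
                       alpha = 0.05, out_dir = tempfile("tcrbrep_")) {
  structure(
    list(ref = ref, qc = qc, min_score = as.integer(min_score),
         region_edges = region_edges, length_weighting = length_weighting,
         alpha = alpha, out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the per-sample pipeline: FASTQ to clonotype table and statistics
#'
#' Reads a FASTQ, applies QC, annotates V/D/J and junctions, assembles the
#' clonotype table, and writes per-sample outputs to
#' `<out_dir>/<sample_id>/`: `airr.tsv` (clonotype table), `qc_report.tsv`,
#' `diversity.tsv`, `v_usage.tsv`, `j_usage.tsv`, `vj_long.tsv`
#' (heatmap-ready long format), and `log.tsv` with record counts at every
#' stage. Outputs are deterministic for identical input.
#'
#' @param config A [run_config()].
#' @param fastq Path to the sample FASTQ.
#' @param sample_id Sample identifier.
#' @param group `"tumor"` or `"normal"`.
#' @param clinical Optional named list of clinical covariates.
#' @return A list: `repertoire`, `profile`, `usage`, `qc`, `status`
#'   (`"ok"` or `"warning"` when no productive clonotypes survive), and
#'   `dir`.
#' @export
run_sample <- function(config, fastq, sample_id,
                       group = c("tumor", "normal"), clinical = NULL) {
  group <- arg_match(group)
  if (!file.exists(fastq)) abort(paste0("unreadable input: ", fastq))
  dir <- file.path(config$out_dir, sample_id)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  raw <- read_fastq(fastq)
  kept <- qc_filter(raw, config$qc)
  qc <- qc_report(kept)
  ann <- annotate_reads(kept, config$ref, min_score = config$min_score)
  ann_counts <- attr(ann, "annotation_counts")
  rep <- build_repertoire(ann, sample_id, group, clinical)

  write_airr(rep, file.path(dir, "airr.tsv"))
  readr::write_tsv(qc, file.path(dir, "qc_report.tsv"))
  profile <- diversity_profile(rep)
  readr::write_tsv(profile, file.path(dir, "diversity.tsv"))

  usage <- vj_usage(rep, config$ref)
  readr::write_tsv(
    tibble(v_call = names(usage$v_usage), frequency = unname(usage$v_usage)),
    file.path(dir, "v_usage.tsv")
  )
  readr::write_tsv(
    tibble(j_call = names(usage$j_usage), frequency = unname(usage$j_usage)),
    file.path(dir, "j_usage.tsv")
  )
  readr::write_tsv(tidy_usage(usage), file.path(dir, "vj_long.tsv"))

  log <- tibble(
    stage = c("raw_reads", "qc_passed", "vj_called", "productive",
              "clonotypes"),
    n = c(qc$n_raw, qc$n_kept, ann_counts$n_called,
          ann_counts$n_productive, nrow(rep))
  )
  readr::write_tsv(log, file.path(dir, "log.tsv"))

  status <- if (nrow(rep) == 0) "warning" else "ok"
  if (status == "warning") {
    warn(paste0("sample ", sample_id, ": no productive clonotypes"))
  }
  list(repertoire = rep, profile = profile, usage = usage, qc = qc,
       log = log, status = status, dir = dir)
}

#' Run the cohort analysis: per-sample statistics to comparison reports
#'
#' Consumes a cohort metadata table (one row per sample: `sample_id`,
#' `group`, clinical covariates, and `airr` paths to per-sample clonotype
#' TSVs) and emits the full report set to `config$out_dir`:
#' `diversity_profiles.tsv`, `diversity_comparison.tsv` (Shannon entropy,
#' clonality, Simpson, CF100, D50, clonotype count, mean CDR3 length),
#' `usage_comparison_{v_family,v_subfamily,j,vj_pair}.tsv`,
#' `vj_mean_{tumor,normal}.tsv` plus `j_clusters_{tumor,normal}.nwk`,
#' `clinical_correlation.tsv`, and `frequency_regions.tsv`.
#'
#' @param config A [run_config()].
#' @param metadata Metadata tibble; each group needs at least 2 samples.
#' @return A list of the report tables (invisibly writes TSVs).
#' @export
run_cohort <- function(config, metadata) {
  stopifnot(all(c("sample_id", "group", "airr") %in% names(metadata)))
  if (any(table(metadata$group) < 2)) {
    abort("each group needs at least 2 samples")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  reps <- purrr::pmap(metadata, function(sample_id, group, airr, ...) {
    clin <- list(...)[intersect(names(list(...)), c("LDH", "NLR", "ALC"))]
    repertoire_from_airr(airr, sample_id, group, clinical = clin)
  })
  names(reps) <- metadata$sample_id

  profiles <- purrr::map_dfr(reps, diversity_profile) %>%
    left_join(select(metadata, sample_id, dplyr::any_of(c("LDH", "NLR", "ALC"))),
              by = "sample_id")
  readr::write_tsv(profiles, file.path(config$out_dir,
                                       "diversity_profiles.tsv"))

  panel <- c("shannon_entropy", "clonality", "simpson", "cf100", "d50",
             "n_clonotypes", "mean_cdr3_len")
  div_cmp <- purrr::map_dfr(panel, ~ compare_diversity(profiles, .x))
  readr::write_tsv(div_cmp, file.path(config$out_dir,
                                      "diversity_comparison.tsv"))

  usage <- usage_by_sample(reps, config$ref)
  usage_cmp <- lapply(
    rlang::set_names(c("v_family", "v_subfamily", "j", "vj_pair")),
    function(lv) {
      res <- compare_usage(usage, level = lv, alpha = config$alpha)
      readr::write_tsv(res, file.path(
        config$out_dir, paste0("usage_comparison_", lv, ".tsv")
      ))
      res
    }
  )

  jclust <- lapply(rlang::set_names(c("tumor", "normal")), function(g) {
    mats <- lapply(reps[metadata$group == g],
                   function(r) vj_usage(r, config$ref)$matrix)
    mean_mat <- Reduce(`+`, mats) / length(mats)
    readr::write_tsv(
      as_tibble(mean_mat, rownames = "v_call"),
      file.path(config$out_dir, paste0("vj_mean_", g, ".tsv"))
    )
    cl <- cluster_j_families(mean_mat)
    writeLines(cl$newick,
               file.path(config$out_dir, paste0("j_clusters_", g, ".nwk")))
    cl
  })

  clin_cor <- purrr::map_dfr(
    intersect(c("LDH", "NLR", "ALC"), names(profiles)),
    function(cv) correlate_clinical(profiles, covariate = cv)
  )
  readr::write_tsv(clin_cor, file.path(config$out_dir,
                                       "clinical_correlation.tsv"))

  regions <- purrr::map_dfr(reps, function(r) {
    fr <- frequency_regions(cdr3_frequencies(r), config$region_edges)
    mutate(fr, sample_id = attr(r, "sample_id"),
           group = attr(r, "group"), .before = 1)
  })
  region_cmp <- regions %>%
    group_by(region) %>%
    dplyr::group_modify(function(d, key) {
      tidy_mw(mann_whitney_u(d$n[d$group == "tumor"],
                             d$n[d$group == "normal"]))
    }) %>%
    ungroup()
  readr::write_tsv(region_cmp, file.path(config$out_dir,
                                         "frequency_regions.tsv"))

  invisible(list(
    profiles = profiles, diversity_comparison = div_cmp,
    usage_comparison = usage_cmp, j_clusters = jclust,
    clinical_correlation = clin_cor, frequency_regions = region_cmp
  ))
}
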