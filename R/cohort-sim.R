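#' Cohort effect template
#'
#' Describes the group-level structure a simulated cohort should carry: V
#' usage shifts in the tumor group, and Spearman couplings (via a Gaussian
#' copula on ranks) between per-sample Shannon entropy and the clinical
#' covariates. The default template mirrors the study conditions: 13 tumor
#' vs 9 normal samples, TRBV16 and TRBV7-6 usage shifted up by +0.05 in
#' tumor, SE-LDH coupling -0.8 in tumor and -0.2 in normal, a positive
#' SE-NLR coupling in tumor, and opposite-signed SE-ALC couplings in the
#' two groups.
#'
#' @param v_shift Named numeric vector of additive usage shifts applied to
#'   the tumor group's V usage (renormalized).
#' @param rho Named list per group of target Spearman correlations between
#'   Shannon entropy and each covariate.
#' @param clone_mean Named per-group mean clone numbers (unique-junction
#'   scale of the study tissues).
#' @param clone_sd Between-sample SD of clone numbers.
#' @return A list of class `cohort_effects`.
#' @export
cohort_effects <- function(v_shift = c(TRBV16 = 0.05, `TRBV7-6` = 0.05),
                           rho = list(
                             tumor = c(LDH = -0.8, NLR = 0.6, ALC = -0.5),
                             normal = c(LDH = -0.2, NLR = 0.2, ALC = 0.3)
                           ),
                           clone_mean = c(tumor = 8900, normal = 7200),
                           clone_sd = 1500) {
  for (g in names(rho)) {
    if (any(abs(rho[[g]]) > 1)) {
      abort("infeasible copula target: |rho| > 1")
    }
  }
  structure(list(v_shift = v_shift, rho = rho, clone_mean = clone_mean,
                 clone_sd = clone_sd),
            class = "cohort_effects")
}

#' @rdname cohort_effects
#' @export
null_effects <- function() {
  cohort_effects(
    v_shift = numeric(0),
    rho = list(tumor = c(LDH = 0, NLR = 0, ALC = 0),
               normal = c(LDH = 0, NLR = 0, ALC = 0)),
    clone_mean = c(tumor = 8000, normal = 8000)
  )
}

# lognormal marginals for the clinical covariates (units: LDH U/L, NLR
# ratio, ALC 10^9/L)
covariate_marginals <- list(
  LDH = c(meanlog = log(220), sdlog = 0.35),
  NLR = c(meanlog = log(2.5), sdlog = 0.4),
  ALC = c(meanlog = log(1.2), sdlog = 0.3)
)

#' Simulate a two-group cohort with known effects
#'
#' Generates per-sample ground-truth repertoires for a tumor/normal cohort.
#' Each sample draws its V/J usage from a Dirichlet centred on the group
#' usage (concentration `params$usage_conc`); the tumor group's centre
#' carries the template's V shifts. Per-sample clone-size skew (log-normal
#' sigma) is driven by a latent Gaussian that also generates the clinical
#' covariates through a Gaussian copula, so the target Spearman couplings
#' between Shannon entropy and LDH/NLR/ALC are built in by construction.
#'
#' @param n_tumor,n_normal Group sizes (defaults 13 and 9, the study
#'   layout).
#' @param effects A [cohort_effects()] template.
#' @param params Base [sim_params()]; per-sample `n_clones`, `clone_sigma`,
#'   `v_usage`, `j_usage` and `seed` are overridden per sample.
#' @param seed Integer seed for the whole cohort.
#' @param ref The `trb_reference`.
#' @param out_dir Optional directory; when given, per-sample FASTQ
#'   (`<sample>.fastq`), ground-truth TSV, a cohort `metadata.tsv` and a
#'   `params.yaml` are written there.
#' @param emit_fastq Write/emit reads (default `TRUE` when `out_dir` is
#'   given). With `FALSE` only clone-level ground truth is generated.
#' @param sequences Generate junction sequences in the truth tables
#'   (default `emit_fastq`); statistical simulations can turn both off.
#' @return A list of class `trb_cohort`: `metadata` (tibble `sample_id`,
#'   `group`, `LDH`, `NLR`, `ALC`, `n_clones`, `clone_sigma`, `fastq`),
#'   `truths` (named list of `trb_truth` tables), `effects`, `seed`.
#' @export
make_cohort <- function(n_tumor = 13L, n_normal = 9L,
                        effects = cohort_effects(),
                        params = sim_params(), seed = 1L,
                        ref = trb_reference(), out_dir = NULL,
                        emit_fastq = !is.null(out_dir),
                        sequences = emit_fastq) {
  set.seed(seed)
  v <- arrange(ref_segments(ref, "V"), id)
  j <- arrange(ref_segments(ref, "J"), id)
  base_v <- setNames(rdirichlet1(rep(2, nrow(v))), v$id)
  base_j <- setNames(rdirichlet1(rep(2, nrow(j))), j$id)

  tumor_v <- base_v
  if (length(effects$v_shift) > 0) {
    tgt <- names(effects$v_shift)
    if (!all(tgt %in% names(tumor_v))) {
      abort("v_shift names a segment outside the reference")
    }
    tumor_v[tgt] <- tumor_v[tgt] + effects$v_shift
    tumor_v <- tumor_v / sum(tumor_v)
  }

  groups <- c(rep("tumor", n_tumor), rep("normal", n_normal))
  sample_ids <- c(sprintf("T%02d", seq_len(n_tumor)),
                  sprintf("N%02d", seq_len(n_normal)))

  meta <- purrr::map_dfr(c("tumor", "normal"), function(g) {
    n <- sum(groups == g)
    z <- rnorm(n) # latent diversity driver: higher z -> higher entropy
    covs <- purrr::imap_dfc(covariate_marginals, function(m, nm) {
      rho_s <- effects$rho[[g]][[nm]] %||% 0
      r <- 2 * sin(pi * rho_s / 6) # Spearman -> Pearson on the copula
      zc <- r * z + sqrt(1 - r^2) * rnorm(n)
      tibble(!!nm := stats::qlnorm(pnorm(zc), m["meanlog"], m["sdlog"]))
    })
    mutate(covs,
      sample_id = sample_ids[groups == g], group = g,
      clone_sigma = 1.5 * exp(-0.35 * z),
      n_clones = pmax(1000L, as.integer(round(
        rnorm(n, effects$clone_mean[[g]], effects$clone_sd)
      ))),
      .before = 1
    )
  }) %>%
    select(sample_id, group, LDH, NLR, ALC, n_clones, clone_sigma)
  meta <- meta[match(sample_ids, meta$sample_id), ]
  meta$fastq <- NA_character_

  sample_seeds <- sample.int(.Machine$integer.max - 1L, nrow(meta))

  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  truths <- vector("list", nrow(meta))
  names(truths) <- meta$sample_id
  for (i in seq_len(nrow(meta))) {
    g <- meta$group[i]
    p <- params
    p$n_clones <- meta$n_clones[i]
    p$clone_sigma <- meta$clone_sigma[i]
    p$seed <- sample_seeds[i]
    centre_v <- if (g == "tumor") tumor_v else base_v
    set.seed(sample_seeds[i])
    p$v_usage <- setNames(rdirichlet1(params$usage_conc * centre_v),
                          names(centre_v))
    p$j_usage <- setNames(rdirichlet1(params$usage_conc * base_j),
                          names(base_j))
    p$seed <- NULL # RNG already positioned for this sample
    truth <- sample_clones(p, ref, sequences = sequences)
    truths[[i]] <- truth
    if (emit_fastq) {
      fq <- file.path(out_dir %||% ".", paste0(meta$sample_id[i], ".fastq"))
      emit_reads(truth, p, ref, fastq_path = fq)
      meta$fastq[i] <- fq
      readr::write_tsv(truth, file.path(
        out_dir %||% ".", paste0(meta$sample_id[i], "_truth.tsv")
      ))
    }
  }
  if (!is.null(out_dir)) {
    readr::write_tsv(meta, file.path(out_dir, "metadata.tsv"))
    yaml::write_yaml(
      list(seed = seed, n_tumor = n_tumor, n_normal = n_normal,
           params = params[!vapply(params, is.null, logical(1))],
           v_shift = as.list(effects$v_shift),
           rho = lapply(effects$rho, as.list)),
      file.path(out_dir, "params.yaml")
    )
  }
  structure(list(metadata = meta, truths = truths, effects = effects,
                 seed = seed),
            class = "trb_cohort")
}

#' Ground-truth usage table of a simulated cohort
#'
#' Clone-frequency-weighted V/J usage per sample, over the full reference
#' gene space, in the long format consumed by [compare_usage()]. This is
#' the noiseless counterpart of [usage_by_sample()]: usage comes from the
#' true clone frequencies rather than from sequenced reads.
#'
#' @param cohort A `trb_cohort` from [make_cohort()].
#' @param ref The `trb_reference` the cohort was simulated from.
#' @return A tibble: `sample_id`, `group`, `level` (`v_subfamily`,
#'   `v_family`, `j`), `gene`, `frequency`.
#' @export
cohort_truth_usage <- function(cohort, ref) {
  v_ids <- sort(ref_segments(ref, "V")$id)
  j_ids <- sort(ref_segments(ref, "J")$id)
  purrr::imap_dfr(cohort$truths, function(truth, sid) {
    g <- cohort$metadata$group[cohort$metadata$sample_id == sid]
    vu <- truth_usage(truth, v_ids, "v")
    vf <- collapse_families(vu)
    ju <- truth_usage(truth, j_ids, "j")
    tibble(
      sample_id = sid, group = g,
      level = c(rep("v_subfamily", length(vu)), rep("v_family", length(vf)),
                rep("j", length(ju))),
      gene = c(names(vu), names(vf), names(ju)),
      frequency = c(unname(vu), unname(vf), unname(ju))
    )
  })
}

# ground-truth usage of one clone table: clone-frequency-weighted V (or J)
# marginal over the reference space
truth_usage <- function(truth, ids, what = c("v", "j")) {
  what <- arg_match(what)
  col <- if (what == "v") truth$v_id else truth$j_id
  u <- vapply(split(truth$true_freq, factor(col, levels = ids)), sum,
              numeric(1))
  u[is.na(u)] <- 0
  u
}
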