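test_that("simulation is fully deterministic under a fixed seed", {
  ref <- trb_reference()
  p <- sim_params(n_clones = 100L, read_depth = 500L, seed = 71L)
  t1 <- sample_clones(p, ref)
  t2 <- sample_clones(p, ref)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  set.seed(5)
  emit_reads(t1, p, ref, fastq_path = f1)
  set.seed(5)
  emit_reads(t2, p, ref, fastq_path = f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("clone tables honour the junction and frequency models", {
  ref <- trb_reference()
  truth <- sample_clones(sim_params(n_clones = 10000L, seed = 72L), ref)
  expect_equal(nrow(truth), 10000)
  expect_equal(sum(truth$true_freq), 1, tolerance = 1e-12)
  expect_true(all(truth$cdr3_len >= 8 & truth$cdr3_len <= 24))
  # empirical mean junction length close to the 14-aa model
  expect_gte(mean(truth$cdr3_len), 13.9)
  expect_lte(mean(truth$cdr3_len), 14.1)
  # every junction is productive C...F by construction
  expect_true(all(is_productive(truth$cdr3_nt)))
  expect_equal(nchar(truth$cdr3_nt), 3L * truth$cdr3_len)
  # embedded D substrings are recorded and mostly recoverable
  with_d <- !is.na(truth$d_id)
  expect_gt(mean(with_d), 0.6)
  expect_lt(mean(with_d), 0.8)
  idx <- which(with_d)[1:200]
  called <- assign_d(truth$cdr3_nt[idx], ref)
  expect_gte(mean(!is.na(called) & called == truth$d_id[idx]), 0.9)
})

test_that("uniform usage vectors are recovered from large clone draws", {
  ref <- trb_reference()
  v_ids <- sort(ref$id[ref$kind == "V"])
  p <- sim_params(
    n_clones = 100000L,
    v_usage = setNames(rep(1 / 58, 58), v_ids),
    seed = 73L
  )
  truth <- sample_clones(p, ref, sequences = FALSE)
  emp <- table(factor(truth$v_id, levels = v_ids)) / nrow(truth)
  expect_lte(max(abs(as.numeric(emp) - 1 / 58)), 0.01)
})

test_that("reads embed the junction verbatim when error-free", {
  ref <- trb_reference()
  p <- sim_params(n_clones = 50L, read_depth = 400L, error_rate = 0,
                  seed = 74L)
  truth <- sample_clones(p, ref)
  reads <- emit_reads(truth, p, ref)
  prov <- attr(reads, "provenance")
  clonal <- !is.na(prov$clone_id)
  cdr3 <- truth$cdr3_nt[match(prov$clone_id[clonal], truth$clone_id)]
  expect_true(all(mapply(grepl, cdr3, reads$seq[clonal], fixed = TRUE)))

  # junk volume follows the binomial model and planted-N junk fails QC
  n_junk <- sum(!clonal)
  expect_lt(abs(n_junk - 400 * p$frac_junk), 3 * sqrt(400 * p$frac_junk) + 3)
  kept <- qc_filter(reads)
  n_with_n <- sum(stringr::str_count(reads$seq, "N") > 8)
  expect_gte(qc_report(kept)$n_removed_ambiguous, n_with_n * 1L)
})

test_that("deep sampling recovers the true clone-frequency entropy", {
  ref <- trb_reference()
  p <- sim_params(n_clones = 300L, read_depth = 6000L, error_rate = 0,
                  frac_junk = 0, degraded_frac = 0, seed = 75L)
  truth <- sample_clones(p, ref, sequences = FALSE)
  counts <- stats::rmultinom(1, p$read_depth, truth$true_freq)[, 1]
  obs <- counts[counts > 0] / sum(counts)
  h_true <- shannon_entropy(truth$true_freq)
  expect_lte(abs(shannon_entropy(obs) - h_true) / h_true, 0.02)
})

test_that("cohorts carry the requested layout, shifts and couplings", {
  ref <- trb_reference()
  dir <- tempfile("cohort_")
  co <- make_cohort(
    n_tumor = 3L, n_normal = 2L,
    params = sim_params(n_clones = 80L, read_depth = 300L),
    seed = 76L, ref = ref, out_dir = dir
  )
  expect_equal(nrow(co$metadata), 5)
  expect_true(all(file.exists(co$metadata$fastq)))
  expect_true(file.exists(file.path(dir, "metadata.tsv")))
  expect_true(file.exists(file.path(dir, "params.yaml")))
  expect_true(all(file.exists(file.path(
    dir, paste0(co$metadata$sample_id, "_truth.tsv")
  ))))
  expect_setequal(unique(co$metadata$group), c("tumor", "normal"))
  expect_true(all(c("LDH", "NLR", "ALC") %in% names(co$metadata)))

  # infeasible copula target is rejected
  expect_error(cohort_effects(rho = list(tumor = c(LDH = -1.2))),
               "infeasible")
})

test_that("the built-in entropy-LDH coupling shows up in generated cohorts", {
  ref <- trb_reference()
  hits <- 0L
  for (r in 1:5) {
    co <- make_cohort(params = sim_params(n_clones = 2000L),
                      seed = 500L + r, ref = ref,
                      emit_fastq = FALSE, sequences = FALSE)
    se <- vapply(co$truths, function(t) shannon_entropy(t$true_freq),
                 numeric(1))
    tum <- co$metadata$group == "tumor"
    rho <- spearman_cor(se[tum], co$metadata$LDH[tum])$rho
    if (rho <= -0.5) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
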