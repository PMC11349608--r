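test_that("Mann-Whitney exact path matches full-enumeration results", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$p_value, 1 / 3,
               tolerance = 1e-12)
  # disjoint ranges, n = 5 vs 5: p = 2 / choose(10, 5)
  expect_equal(mann_whitney_u(1:5, 6:10)$p_value, 2 / 252,
               tolerance = 1e-12)
  # identical multisets -> p = 1 by symmetry (tie-corrected path, z = 0)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  # cross-check against the independent exact implementation in wilcox.test
  set.seed(14)
  for (nx in 1:4) {
    for (ny in 1:(8 - nx)) {
      if (ny < 1) next
      x <- rnorm(nx)
      y <- rnorm(ny)
      ours <- mann_whitney_u(x, y)
      expect_equal(ours$method, "exact")
      expect_equal(ours$p_value, wilcox.test(x, y, exact = TRUE)$p.value,
                   tolerance = 1e-12, info = paste(nx, ny))
      expect_equal(ours$u_statistic,
                   unname(wilcox.test(x, y, exact = TRUE)$statistic))
    }
  }
})

test_that("Mann-Whitney normal path matches the tie/continuity-corrected form", {
  set.seed(15)
  for (i in 1:50) {
    x <- sample(1:6, 9, replace = TRUE)
    y <- sample(1:6, 13, replace = TRUE)
    ours <- mann_whitney_u(x, y)
    expect_equal(ours$method, "normal")
    ref_p <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    )
    expect_equal(ours$p_value, ref_p, tolerance = 1e-10)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("Spearman correlation reproduces hand-computed ranks", {
  expect_equal(spearman_cor(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_cor(1:8, -(1:8))$rho, -1)
  # d^2 = (0,1,1,1,1): rho = 1 - 6*4/(5*24) = 0.8
  expect_equal(spearman_cor(1:5, c(1, 3, 2, 5, 4))$rho, 0.8,
               tolerance = 1e-12)
  # rank invariance
  set.seed(16)
  x <- rnorm(20)
  y <- rnorm(20)
  expect_equal(spearman_cor(x, y)$rho,
               spearman_cor(rank(x), rank(y))$rho, tolerance = 1e-12)
  # cross-check rho and t-approximation p against cor.test
  ct <- cor.test(x, y, method = "spearman", exact = FALSE)
  ours <- spearman_cor(x, y)
  expect_equal(ours$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(ours$p_value, ct$p.value, tolerance = 1e-9)

  expect_error(spearman_cor(1:2, 1:2), "at least 3")
  expect_error(spearman_cor(1:5, rep(2, 5)), "zero rank variance")
})

test_that("compare_diversity applies the rank test to profile columns", {
  profiles <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:10),
    group = rep(c("tumor", "normal"), each = 5),
    cf100 = c(0.9, 0.8, 0.85, 0.95, 0.88, 0.2, 0.3, 0.25, 0.15, 0.28)
  )
  res <- compare_diversity(profiles, "cf100")
  expect_equal(res$metric, "cf100")
  expect_equal(res$p_value, 2 / 252, tolerance = 1e-12)
  expect_equal(res$n_a, 5)
  expect_false(anyNA(res$mean_a))
  expect_error(compare_diversity(profiles, "nope"), "unknown metric")
})

test_that("usage comparison covers the gene space with monotone BH values", {
  ref <- trb_reference()
  set.seed(77)
  co <- make_cohort(n_tumor = 6L, n_normal = 5L,
                    params = sim_params(n_clones = 600L), seed = 77L,
                    ref = ref, emit_fastq = FALSE, sequences = FALSE)
  usage <- cohort_truth_usage(co, ref)
  res_v <- compare_usage(usage, "v_subfamily")
  expect_equal(nrow(res_v), 58)
  res_f <- compare_usage(usage, "v_family")
  expect_equal(nrow(res_f), 28)
  res_j <- compare_usage(usage, "j")
  expect_equal(nrow(res_j), 14)
  expect_true(all(res_v$p_adjusted >= res_v$p_value - 1e-12))
  # BH is monotone in the raw p ordering
  ord <- order(res_v$p_value)
  expect_true(all(diff(res_v$p_adjusted[ord]) >= -1e-12))
})

test_that("vj_pair-level comparison yields one row per matrix cell", {
  ref <- trb_reference()
  reps <- lapply(1:4, function(i) {
    ann <- tibble::tibble(
      read_id = sprintf("r%d_%d", i, 1:20),
      v_call = sample(c("TRBV16", "TRBV7-6"), 20, TRUE),
      d_call = NA_character_,
      j_call = sample(c("TRBJ2-1", "TRBJ1-1"), 20, TRUE),
      cdr3_nt = "TGTGCCAGCTTT", cdr3_aa = "CASF",
      productive = TRUE, v_score = 20L, j_score = 15L
    )
    build_repertoire(ann, paste0("s", i), if (i <= 2) "tumor" else "normal")
  })
  usage <- usage_by_sample(reps, ref)
  res <- compare_usage(usage, "vj_pair")
  expect_equal(nrow(res), 812)
})

test_that("clinical correlation runs per group and validates covariates", {
  profiles <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:12),
    group = rep(c("tumor", "normal"), each = 6),
    shannon_entropy = c(6:1, 1:6),
    LDH = c(1:6, 6:1) * 50,
    NLR = c(rep(2, 6), 1:6)
  )
  res <- correlate_clinical(profiles, covariate = "LDH")
  expect_equal(nrow(res), 2)
  expect_equal(res$rho[res$group == "tumor"], -1)
  expect_equal(res$rho[res$group == "normal"], -1)
  # constant covariate -> undefined correlation
  expect_error(correlate_clinical(profiles[profiles$group == "tumor", ],
                                  covariate = "NLR"),
               "zero rank variance")
  profiles$NLR[2] <- NA
  expect_error(correlate_clinical(profiles, covariate = "NLR"), "s02")
  expect_error(correlate_clinical(profiles, covariate = "ALC"),
               "missing covariate")
})

test_that("J-family clustering recovers block structure deterministically", {
  # two exact blocks of J columns
  m <- matrix(0, nrow = 6, ncol = 6,
              dimnames = list(paste0("TRBV", 1:6),
                              c(paste0("TRBJ1-", 1:3), paste0("TRBJ2-", 1:3))))
  m[1:3, 1:3] <- 0.1
  m[4:6, 4:6] <- 0.12
  cl <- cluster_j_families(m)
  groups <- split(names(cl$clusters), cl$clusters)
  expect_setequal(groups[[1]], paste0("TRBJ1-", 1:3))
  expect_setequal(groups[[2]], paste0("TRBJ2-", 1:3))
  # newick output parses back to the same 6 tips
  tree <- ape::read.tree(text = cl$newick)
  expect_setequal(tree$tip.label, colnames(m))

  # hand-computable linkage: two close columns merge before the far one
  m3 <- cbind(a = c(0, 0), b = c(1, 0), c = c(10, 0))
  cl3 <- cluster_j_families(m3)
  expect_equal(sort(unname(cl3$clusters[c("a", "b")])), c(1, 1))
  expect_equal(unname(cl3$clusters["c"]), 2)

  # degenerate: all columns identical
  m_id <- matrix(0.5, 3, 3, dimnames = list(NULL, c("x", "y", "z")))
  expect_silent(cluster_j_families(m_id))
})
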