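make_rep <- function(cdr3_aa, v_call, j_call, count,
                     sample_id = "s1", group = "tumor") {
  v_call <- rep_len(v_call, length(cdr3_aa))
  j_call <- rep_len(j_call, length(cdr3_aa))
  ann <- tibble::tibble(
    read_id = sprintf("r%05d", seq_len(sum(count))),
    v_call = rep(v_call, count), d_call = NA_character_,
    j_call = rep(j_call, count),
    cdr3_nt = NA_character_,
    cdr3_aa = rep(cdr3_aa, count),
    productive = TRUE, v_score = 20L, j_score = 15L
  )
  # cdr3_nt is irrelevant for these statistics; reuse the aa string
  ann$cdr3_nt <- ann$cdr3_aa
  build_repertoire(ann, sample_id, group)
}

test_that("length distribution recovers degenerate and symmetric cases", {
  rep14 <- make_rep(c("CASSLGQGAETQYF", "CASSLGQGAETQWF"), "TRBV16",
                    "TRBJ2-1", c(3L, 2L))
  ld <- length_distribution(rep14)
  expect_equal(ld$mean, 14)
  expect_equal(ld$sd, 0)

  # two lengths 13 and 15 equally weighted -> mean 14
  rep2 <- make_rep(c("CASSLGQGAETQF", "CASSLGQGAETQWYF"), "TRBV16",
                   "TRBJ2-1", c(1L, 1L))
  expect_equal(length_distribution(rep2)$mean, 14)
})

test_that("simulated junction lengths are Gaussian around 14 aa", {
  ref <- trb_reference()
  truth <- sample_clones(sim_params(n_clones = 5000L, seed = 303L), ref)
  rep <- build_repertoire(
    tibble::tibble(
      read_id = truth$clone_id, v_call = truth$v_id, d_call = truth$d_id,
      j_call = truth$j_id, cdr3_nt = truth$cdr3_nt,
      cdr3_aa = truth$cdr3_aa, productive = TRUE, v_score = 20L,
      j_score = 15L
    ),
    "sim", "tumor"
  )
  ld <- length_distribution(rep)
  expect_gte(ld$mean, 13.8)
  expect_lte(ld$mean, 14.2)
  expect_gte(ld$gaussian_fit_r2, 0.95)
})

test_that("frequency regions use half-open decade bins and conserve counts", {
  fr <- frequency_regions(c(0.0005, 0.001, 0.9985))
  expect_equal(sum(fr$n), 3)
  # 0.0005 and exactly 1e-3 both land in the 0.01%-0.1% region (1e-4, 1e-3]
  expect_equal(fr$n[fr$lo == 1e-4], 2)

  # exactly 1e-2 belongs to (1e-3, 1e-2] under the half-open rule
  uni <- frequency_regions(rep(0.01, 100))
  expect_equal(uni$n[uni$lo == 1e-3], 100)
  # frequencies strictly above a decade edge move up a region
  uni50 <- frequency_regions(rep(0.02, 50))
  expect_equal(uni50$n[uni50$lo == 1e-2], 50)

  expect_error(frequency_regions(c(0.5, 1.2)), "\\(0, 1\\]")
  expect_error(frequency_regions(numeric(0)), "empty")

  set.seed(17)
  for (i in 1:10) {
    p <- stats::rgamma(sample(10:2000, 1), 0.2)
    p <- p / sum(p)
    expect_equal(sum(frequency_regions(p)$n), length(p))
  }
})

test_that("vj_usage spans the full 812-cell space with unit mass", {
  ref <- trb_reference()
  rep <- make_rep("CASSF", "TRBV16", "TRBJ2-1", 10L)
  u <- vj_usage(rep, ref)
  expect_equal(dim(u$matrix), c(58L, 14L))
  expect_equal(length(u$matrix), 812L)
  expect_equal(u$matrix["TRBV16", "TRBJ2-1"], 1)
  expect_equal(sum(u$matrix), 1, tolerance = 1e-9)
  expect_equal(u$n_vj_pairs, 1L)
  expect_equal(sum(u$v_usage), 1, tolerance = 1e-9)

  bad <- make_rep("CASSF", "TRBVX9", "TRBJ2-1", 1L)
  expect_error(vj_usage(bad, ref), "outside the reference")
})

test_that("empirical usage converges to the sampling probabilities", {
  ref <- trb_reference()
  set.seed(404)
  v_ids <- sort(ref$id[ref$kind == "V"])
  j_ids <- sort(ref$id[ref$kind == "J"])
  p_v <- setNames(rep(1 / 58, 58), v_ids)
  p_j <- setNames(rep(1 / 14, 14), j_ids)
  n <- 1e5
  draw_v <- sample(v_ids, n, replace = TRUE, prob = p_v)
  draw_j <- sample(j_ids, n, replace = TRUE, prob = p_j)
  ann <- tibble::tibble(
    read_id = sprintf("r%06d", 1:n), v_call = draw_v, d_call = NA_character_,
    j_call = draw_j, cdr3_nt = "TGTGCCAGCTTT", cdr3_aa = "CASF",
    productive = TRUE, v_score = 20L, j_score = 15L
  )
  u <- vj_usage(build_repertoire(ann, "s", "tumor"), ref)
  expect_lte(max(abs(u$matrix - (1 / 58) * (1 / 14))), 0.01)
  expect_lte(max(abs(u$v_usage - 1 / 58)), 0.01)
})

test_that("overlap rate is the overlap coefficient on unique junctions", {
  a <- make_rep(c("CAX1F", "CAX2F", "CAX3F", "CAX4F"), "TRBV16", "TRBJ2-1",
                rep(1L, 4))
  b <- make_rep(c("CAX1F", "CAX2F", "CAX9F"), "TRBV16", "TRBJ2-1",
                rep(1L, 3))
  expect_equal(overlap_rate(a, b), 2 / 3)
  expect_equal(overlap_rate(a, a), 1)
  disj <- make_rep(c("CAY1F", "CAY2F"), "TRBV16", "TRBJ2-1", rep(1L, 2))
  expect_equal(overlap_rate(a, disj), 0)
  empty <- build_repertoire(
    tibble::tibble(read_id = "r", v_call = "x", d_call = NA, j_call = "y",
                   cdr3_nt = "TGA", cdr3_aa = "*", productive = FALSE,
                   v_score = 1L, j_score = 1L),
    "e", "tumor"
  )
  expect_error(overlap_rate(a, empty), "empty")
})
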