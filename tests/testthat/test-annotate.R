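test_that("error-free reads are annotated with the true segments and junction", {
  ref <- toy_reference()
  # interior encodes ASSLG (no stop, in frame)
  rd <- toy_read(ref, "TRBV1", "TRBJ1-2", "GCCAGCAGCTTAGGG")
  reads <- tibble::tibble(read_id = "r1", seq = rd$read,
                          qual = strrep("I", nchar(rd$read)))
  ann <- annotate_reads(reads, ref)
  expect_equal(ann$v_call, "TRBV1")
  expect_equal(ann$j_call, "TRBJ1-2")
  expect_equal(ann$cdr3_nt, rd$cdr3_nt)
  expect_equal(ann$cdr3_aa, rd$cdr3_aa)
  expect_true(ann$productive)
  expect_equal(nchar(ann$cdr3_nt), 3 * nchar(ann$cdr3_aa))
  expect_match(ann$cdr3_aa, "^C.*F$")
})

test_that("assign_vj respects the downstream-J constraint and tie-breaks", {
  ref <- toy_reference()
  rd <- toy_read(ref, "TRBV2", "TRBJ1-1", "GCCAGCAGC")
  hits <- assign_vj(rd$read, ref)
  expect_equal(hits$v$segment_id, "TRBV2")
  expect_equal(hits$j$segment_id, "TRBJ1-1")
  expect_gte(hits$j$read_start, hits$v$read_end)

  # two V entries with identical sequence: lexicographically smaller id wins
  fa <- tempfile(fileext = ".fasta")
  v <- paste0(strrep("GATC", 5), "TGC", "ACT")
  j <- paste0("ACACAC", "TTC", "GGGTTTAAACCCGGG")
  writeLines(c(">TRBV11", v, ">TRBV3", v, ">TRBJ1-1", j), fa)
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("id\tkind\tanchor_nt", "TRBV11\tV\t20", "TRBV3\tV\t20",
               "TRBJ1-1\tJ\t6"), tsv)
  dup <- load_reference(fa, tsv)
  rd2 <- toy_read(dup, "TRBV3", "TRBJ1-1", "GCCAGCAGC")
  expect_equal(assign_vj(rd2$read, dup)$v$segment_id, "TRBV11")
})

test_that("random reads never produce productive annotations", {
  # chance local alignments of random 100-mers occasionally clear the
  # score-10 threshold (the expected best score over the 58-V search space
  # is about ln(Knm)/lambda ~ 10), but a spurious V+J call still cannot
  # yield an in-frame C...F junction, so no clonotype is ever fabricated
  ref <- trb_reference()
  set.seed(99)
  reads <- tibble::tibble(
    read_id = sprintf("r%03d", 1:200),
    seq = vapply(1:200, function(i) random_nt(100), character(1)),
    qual = strrep("I", 100)
  )
  ann <- annotate_reads(reads, ref)
  expect_false(any(ann$productive))
  expect_lt(attr(ann, "annotation_counts")$n_called / nrow(ann), 0.25)
  rep <- build_repertoire(ann, "junk", "tumor")
  expect_equal(nrow(rep), 0)
})

test_that("junction extraction translates correctly and flags productivity", {
  expect_equal(tcrbrep:::translate_nt("TGTGCCAGCTTT"), "CASF")
  expect_true(is_productive("TGTGCCAGCTTT"))
  expect_false(is_productive("TGTTAGTTT"))   # internal stop
  expect_false(is_productive("TGTGCCTT"))    # length not divisible by 3
  expect_false(is_productive("GCCGCCTTT"))   # does not start with C
  expect_false(is_productive(NA_character_))
})

test_that("D assignment needs a unique best match of at least 5 nt", {
  ref <- toy_reference() # TRBD1 = GGGACAGGGG
  # 8-nt run copied from TRBD1 inside the junction
  expect_equal(assign_d("TGTAAGGGACAGGGTTT", ref), "TRBD1")
  # no shared 5-mer
  expect_true(is.na(assign_d("TGTCTCTCTCTCTTT", ref)))

  # two D segments, equal-length best matches -> ambiguous, NA
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">TRBV1", paste0(strrep("GATC", 5), "TGC", "ACT"),
               ">TRBD1", "GGGGGATTTTTAT", ">TRBD2", "CCCCCATTATTAT",
               ">TRBJ1-1", paste0("ACACAC", "TTC", "GGGTTTAAACCCGGG")), fa)
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("id\tkind\tanchor_nt", "TRBV1\tV\t20", "TRBD1\tD\t",
               "TRBD2\tD\t", "TRBJ1-1\tJ\t6"), tsv)
  two_d <- load_reference(fa, tsv)
  # junction contains GGGGG (from D1) and CCCCC (from D2), both length 5
  expect_true(is.na(assign_d("TGTGGGGGTAACCCCCTTT", two_d)))
})

test_that("build_repertoire groups by (cdr3_aa, v, j) and conserves reads", {
  ann <- tibble::tibble(
    read_id = sprintf("r%02d", 1:12),
    v_call = c(rep("TRBV16", 10), "TRBV7-6", "TRBV16"),
    d_call = NA_character_,
    j_call = "TRBJ2-1",
    cdr3_nt = "TGTGCCAGCAGCTTT",
    cdr3_aa = c(rep("CASSF", 11), "CAWF"),
    productive = c(rep(TRUE, 11), FALSE),
    v_score = 20L, j_score = 15L
  )
  rep <- build_repertoire(ann, "s1", "tumor")
  # 10 identical productive reads -> one clonotype; same aa under a
  # different V is a distinct row; the non-productive read is dropped
  expect_equal(nrow(rep), 2)
  expect_equal(sum(rep$count), 11)
  expect_equal(sum(rep$count), attr(rep, "total_productive_reads"))
  expect_equal(sum(rep$frequency), 1, tolerance = 1e-9)
  expect_equal(rep$count[rep$v_call == "TRBV16"], 10)

  # single clonotype -> frequency 1
  one <- build_repertoire(ann[1:10, ], "s2", "normal")
  expect_equal(nrow(one), 1)
  expect_equal(one$frequency, 1)

  # zero productive annotations -> empty repertoire
  empty <- build_repertoire(ann[12, ], "s3", "tumor")
  expect_equal(nrow(empty), 0)
  expect_equal(diversity_profile(empty)$n_clonotypes, 0)
})

test_that("V calls stay accurate under sequencing errors", {
  ref <- trb_reference()
  p <- sim_params(n_clones = 400L, read_depth = 1000L, error_rate = 0.005,
                  frac_junk = 0, degraded_frac = 0, seed = 202L)
  truth <- sample_clones(p, ref)
  reads <- emit_reads(truth, p, ref)
  ann <- annotate_reads(reads, ref)
  prov <- attr(reads, "provenance")
  j <- dplyr::left_join(ann, prov, by = "read_id")
  j <- dplyr::left_join(j, truth, by = "clone_id")
  acc <- mean(j$v_call == j$v_id)
  expect_gte(acc, 0.95)
})
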