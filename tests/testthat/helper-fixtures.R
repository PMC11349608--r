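# Shared fixtures: a tiny hand-built germline reference, read constructors,
# and independent brute-force oracles.

# two V, one D, two J segments with known anchors
toy_reference <- function() {
  v1 <- paste0("GGAACCTTGGAACCTTGGAA", "TGC", "ACT")           # anchor 20
  v2 <- paste0("CCTTAAGGCCTTAAGGCCTT", "TGT", "GTA")           # anchor 20
  j1 <- paste0("ACACAC", "TTC", "GGGTTTAAACCCGGG")             # anchor 6
  j2 <- paste0("GTGTGT", "TTT", "CCCAAATTTGGGCCC")             # anchor 6
  d1 <- "GGGACAGGGG"
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">TRBV1", v1, ">TRBV2", v2, ">TRBD1", d1,
               ">TRBJ1-1", j1, ">TRBJ1-2", j2), fa)
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("id\tkind\tanchor_nt",
               "TRBV1\tV\t20", "TRBV2\tV\t20", "TRBD1\tD\t",
               "TRBJ1-1\tJ\t6", "TRBJ1-2\tJ\t6"), tsv)
  load_reference(fa, tsv)
}

# build an error-free amplicon read: V through its anchor codon, junction
# interior, J from its anchor codon on (cdr3_nt includes both anchor codons)
toy_read <- function(ref, v_id, j_id, interior_nt) {
  v <- ref[ref$id == v_id, ]
  j <- ref[ref$id == j_id, ]
  v_codon <- substr(v$seq_nt, v$anchor_nt + 1, v$anchor_nt + 3)
  j_codon <- substr(j$seq_nt, j$anchor_nt + 1, j$anchor_nt + 3)
  cdr3 <- paste0(v_codon, interior_nt, j_codon)
  read <- paste0(
    substr(v$seq_nt, 1, v$anchor_nt), cdr3,
    substr(j$seq_nt, j$anchor_nt + 4, nchar(j$seq_nt))
  )
  list(read = read, cdr3_nt = cdr3, cdr3_aa = translate_nt_test(cdr3))
}

translate_nt_test <- function(nt) {
  # independent translation via Biostrings for fixture construction
  as.character(Biostrings::translate(Biostrings::DNAString(nt)))
}

fastq_file <- function(ids, seqs, quals) {
  f <- tempfile(fileext = ".fastq")
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), f)
  f
}

# --- independent oracles ------------------------------------------------

# global (Needleman-Wunsch) score: match +1, mismatch -1, linear gap -2
nw_score <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  prev <- seq(0, -2 * m, by = -2)
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    cur[1] <- -2 * i
    for (j in seq_len(m)) {
      cur[j + 1] <- max(
        prev[j] + ifelse(A[i] == B[j], 1, -1),
        prev[j + 1] - 2,
        cur[j] - 2
      )
    }
    prev <- cur
  }
  prev[m + 1]
}

# brute-force best local score: max global score over all substring pairs
bf_local_score <- function(a, b) {
  best <- 0
  na <- nchar(a)
  nb <- nchar(b)
  for (i1 in seq_len(na)) {
    for (i2 in i1:na) {
      sa <- substr(a, i1, i2)
      for (j1 in seq_len(nb)) {
        for (j2 in j1:nb) {
          s <- nw_score(sa, substr(b, j1, j2))
          if (s > best) best <- s
        }
      }
    }
  }
  best
}

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
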