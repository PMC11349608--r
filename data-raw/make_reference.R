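# One-time generator for the bundled synthetic germline reference.
# 58 V segments in 28 families (TRBV7 holds 8 subfamilies), 2 D, 14 J
# (including the pseudogene-style TRBJ2-2p). Run from the repo root:
#   Rscript data-raw/make_reference.R
set.seed(20240827L)

singletons <- paste0("TRBV", c(1, 2, 9, 13:25, 27:30))
multi <- list(TRBV3 = 2, TRBV4 = 3, TRBV5 = 8, TRBV6 = 9, TRBV7 = 8,
              TRBV10 = 3, TRBV11 = 3, TRBV12 = 2)
v_ids <- c(singletons,
           unlist(lapply(names(multi), function(f)
             paste0(f, "-", seq_len(multi[[f]])))))
stopifnot(length(v_ids) == 58, length(unique(sub("-.*$", "", v_ids))) == 28)

j_ids <- c(paste0("TRBJ1-", 1:6), paste0("TRBJ2-", 1:7), "TRBJ2-2p")
stopifnot(length(j_ids) == 14)

rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

# V: 60 nt, conserved Cys codon at 0-based offset 54 ([54,57)), 3 nt tail.
v_seqs <- vapply(seq_along(v_ids), function(i) {
  body <- rand_nt(54)
  cys <- if (i %% 2 == 0) "TGT" else "TGC"
  paste0(body, cys, rand_nt(3))
}, character(1))

# J: 48 nt, conserved Phe codon at 0-based offset 9 ([9,12)).
j_seqs <- vapply(seq_along(j_ids), function(i) {
  phe <- if (i %% 2 == 0) "TTT" else "TTC"
  paste0(rand_nt(9), phe, rand_nt(36))
}, character(1))

# Short G-rich D segments; no shared 5-mer between the two, no frame-0 stops.
d_ids <- c("TRBD1", "TRBD2")
d_seqs <- c("GGCACAGGGGGC", "GGGACTAGCGGGAGGG")

stopifnot(!anyDuplicated(c(v_seqs, j_seqs, d_seqs)))

ids <- c(v_ids, d_ids, j_ids)
seqs <- c(v_seqs, d_seqs, j_seqs)
kind <- c(rep("V", 58), rep("D", 2), rep("J", 14))
anchor <- c(rep(54L, 58), rep(NA_integer_, 2), rep(9L, 14))

fa <- file("inst/extdata/trb_synthetic_reference.fasta", "w")
for (i in seq_along(ids)) cat(">", ids[i], "\n", seqs[i], "\n", sep = "", file = fa)
close(fa)

tab <- data.frame(id = ids, kind = kind, anchor_nt = anchor)
write.table(tab, "inst/extdata/trb_synthetic_anchors.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE, na = "")
cat("wrote", length(ids), "segments\n")
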