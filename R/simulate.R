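#' Simulation parameters for the repertoire generator
#'
#' Defaults emulate the statistical structure of the study tissue data:
#' about 10^3-10^4 unique junctions per sample with a skewed (log-normal)
#' clone-size distribution, CDR3 amino-acid lengths ~ round(Normal(14,
#' 1.5)) clipped to `[8, 24]`, skewed V/J usage drawn from a Dirichlet when
#' not supplied, 5e4 reads per sample with a per-base substitution error
#' rate of 0.002, Phred qualities centred at 38 with a degraded low-quality
#' tail, and 1% junk reads to exercise QC and no-call handling.
#'
#' @param n_clones Number of clones (default 8000).
#' @param clone_sigma Log-normal sigma of unnormalized clone weights
#'   (default 1.5).
#' @param v_usage,j_usage Optional named probability vectors over the
#'   reference V/J segments; when `NULL`, a Dirichlet(1) draw is made at
#'   generation time under the params seed.
#' @param cdr3_len_mean,cdr3_len_sd Junction length model in amino acids
#'   (default 14 and 1.5); lengths are rounded and clipped to `len_range`.
#' @param len_range Length clip range (default `c(8, 24)`).
#' @param read_depth Reads per sample (default 5e4).
#' @param error_rate Per-base substitution probability (default 0.002).
#' @param qual_mean,qual_sd Phred quality model for clean reads (default
#'   38, 3).
#' @param degraded_frac Fraction of clone reads emitted with degraded
#'   qualities (mean Phred 20) so that QC has work to do (default 0.005).
#' @param frac_junk Fraction of junk reads: random sequence, a third
#'   carrying 9 N bases, a third degraded-quality, a third clean random
#'   (default 0.01).
#' @param d_embed_prob Probability that a clone junction embeds a
#'   codon-aligned 6- or 9-nt D-segment substring (default 0.7).
#' @param usage_conc Dirichlet concentration for per-sample usage draws in
#'   cohorts (default 100).
#' @param seed Optional integer seed applied at generation time.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_clones = 8000L, clone_sigma = 1.5,
                       v_usage = NULL, j_usage = NULL,
                       cdr3_len_mean = 14, cdr3_len_sd = 1.5,
                       len_range = c(8L, 24L),
                       read_depth = 50000L, error_rate = 0.002,
                       qual_mean = 38, qual_sd = 3,
                       degraded_frac = 0.005, frac_junk = 0.01,
                       d_embed_prob = 0.7, usage_conc = 100,
                       seed = NULL) {
  stopifnot(n_clones >= 1, clone_sigma >= 0, read_depth >= 1,
            error_rate >= 0, error_rate <= 1,
            frac_junk >= 0, frac_junk <= 1,
            d_embed_prob >= 0, d_embed_prob <= 1,
            len_range[1] >= 3, len_range[1] <= len_range[2])
  for (u in list(v_usage, j_usage)) {
    if (!is.null(u)) stopifnot(abs(sum(u) - 1) < 1e-6, all(u >= 0))
  }
  structure(as.list(environment())[names(formals(sim_params))],
            class = "sim_params")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

# frame-0 stop-free substrings of each D segment, lengths 6 and 9,
# used for codon-aligned embedding into junction interiors
d_safe_substrings <- function(ref) {
  d <- ref_segments(ref, "D")
  lapply(setNames(d$seq_nt, d$id), function(s) {
    out <- character(0)
    for (l in c(6L, 9L)) {
      if (nchar(s) < l) next
      subs <- substring(s, 1:(nchar(s) - l + 1L), l:nchar(s))
      keep <- !stringr::str_detect(translate_nt(subs), stringr::fixed("*"))
      out <- c(out, subs[keep])
    }
    out
  })
}

#' Draw a ground-truth clone table
#'
#' Samples V and J per clone from the usage vectors, draws junction lengths
#' from the Gaussian length model, builds junction nucleotides as the V
#' segment's conserved Cys codon + a uniformly back-translated random
#' interior + the J segment's conserved Phe codon, and with probability
#' `d_embed_prob` overwrites a codon-aligned interior stretch with a 6- or
#' 9-nt D-segment substring (recorded as the true D). Clone frequencies are
#' normalized log-normal weights.
#'
#' @param params A [sim_params()] object.
#' @param ref The `trb_reference` to simulate from.
#' @param sequences Generate junction sequences (default TRUE). With
#'   `FALSE` only V/J assignments, lengths and frequencies are drawn -
#'   sufficient for statistical cohort simulations and much faster.
#' @return A tibble of class `trb_truth`: `clone_id`, `v_id`, `d_id`,
#'   `j_id`, `cdr3_len`, `cdr3_nt`, `cdr3_aa`, `true_freq` (sums to 1).
#' @export
sample_clones <- function(params = sim_params(), ref = trb_reference(),
                          sequences = TRUE) {
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_clones
  v <- arrange(ref_segments(ref, "V"), id)
  j <- arrange(ref_segments(ref, "J"), id)
  v_usage <- params$v_usage %||%
    setNames(rdirichlet1(rep(1, nrow(v))), v$id)
  j_usage <- params$j_usage %||%
    setNames(rdirichlet1(rep(1, nrow(j))), j$id)
  v_usage <- v_usage[v$id]
  j_usage <- j_usage[j$id]

  v_idx <- sample.int(nrow(v), n, replace = TRUE, prob = v_usage)
  j_idx <- sample.int(nrow(j), n, replace = TRUE, prob = j_usage)
  w <- rlnorm(n, 0, params$clone_sigma)
  freq <- w / sum(w)
  len <- pmin(pmax(round(rnorm(n, params$cdr3_len_mean, params$cdr3_len_sd)),
                   params$len_range[1]), params$len_range[2])

  out <- tibble(
    clone_id = sprintf("clone_%05d", seq_len(n)),
    v_id = v$id[v_idx],
    d_id = NA_character_,
    j_id = j$id[j_idx],
    cdr3_len = as.integer(len),
    cdr3_nt = NA_character_,
    cdr3_aa = NA_character_,
    true_freq = freq
  )

  if (sequences) {
    codons <- sense_codons_by_aa()
    aa_letters <- names(codons)
    flat <- unlist(codons, use.names = FALSE)
    n_cod <- lengths(codons)
    offset <- cumsum(c(0L, n_cod[-length(n_cod)]))
    names(offset) <- aa_letters

    int_len <- len - 2L
    total <- sum(int_len)
    aa_draw <- sample(aa_letters, total, replace = TRUE)
    cod_draw <- flat[offset[aa_draw] +
                       ceiling(runif(total) * n_cod[aa_draw])]
    interior <- vapply(
      split(cod_draw, rep(seq_len(n), int_len)),
      paste, character(1), collapse = ""
    )
    interior <- unname(interior[order(as.integer(names(interior)))])

    embed <- runif(n) < params$d_embed_prob
    d_subs <- d_safe_substrings(ref)
    if (length(d_subs) > 0 && any(embed)) {
      which_d <- sample(names(d_subs), sum(embed), replace = TRUE)
      idx_embed <- which(embed)
      for (i in seq_along(idx_embed)) {
        cl <- idx_embed[i]
        pool <- d_subs[[which_d[i]]]
        pool <- pool[nchar(pool) <= 3L * int_len[cl]]
        if (length(pool) == 0) next
        s <- pool[sample.int(length(pool), 1L)]
        max_cod <- int_len[cl] - nchar(s) / 3L
        at <- sample.int(max_cod + 1L, 1L) - 1L # codon offset
        substr(interior[cl], 3L * at + 1L, 3L * at + nchar(s)) <- s
        out$d_id[cl] <- which_d[i]
      }
    }

    v_codon <- substr(v$seq_nt[v_idx], v$anchor_nt[v_idx] + 1L,
                      v$anchor_nt[v_idx] + 3L)
    j_codon <- substr(j$seq_nt[j_idx], j$anchor_nt[j_idx] + 1L,
                      j$anchor_nt[j_idx] + 3L)
    out$cdr3_nt <- paste0(v_codon, interior, j_codon)
    out$cdr3_aa <- translate_nt(out$cdr3_nt)
  }
  structure(out, v_usage = v_usage, j_usage = j_usage,
            class = c("trb_truth", class(out)))
}

qual_string <- function(n, mean, sd) {
  q <- pmin(pmax(round(rnorm(n, mean, sd)), 2L), 41L)
  intToUtf8(q + 33L)
}

mutate_bases <- function(seq, rate) {
  n <- nchar(seq)
  k <- rbinom(1L, n, rate)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  for (p in pos) {
    cur <- substr(seq, p, p)
    sub <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    substr(seq, p, p) <- sub
  }
  seq
}

#' Emit sequencing reads from a ground-truth clone table
#'
#' Each clonal read is the clone's V segment up to and including the Cys
#' anchor codon, the junction interior, and the J segment from the Phe
#' anchor codon onward, with substitution errors at `error_rate` and Phred
#' qualities from the quality model. Read counts per clone are multinomial
#' over the true frequencies. `frac_junk` junk reads (random sequence; a
#' third planted with 9 N bases, a third degraded-quality, a third clean)
#' are appended and shuffled in.
#'
#' @param truth A `trb_truth` table from [sample_clones()] (with
#'   sequences).
#' @param params The same [sim_params()] used for the truth.
#' @param ref The same `trb_reference`.
#' @param fastq_path Optional path; when given, reads are also written as
#'   Phred+33 FASTQ.
#' @return A read tibble (`read_id`, `seq`, `qual`) with a `provenance`
#'   attribute: tibble `read_id`, `clone_id` (`NA` for junk).
#' @export
emit_reads <- function(truth, params, ref = trb_reference(),
                       fastq_path = NULL) {
  if (anyNA(truth$cdr3_nt)) {
    abort("truth table has no sequences; rerun sample_clones(sequences = TRUE)")
  }
  v <- ref_segments(ref, "V")
  j <- ref_segments(ref, "J")
  v_prefix <- setNames(substr(v$seq_nt, 1L, v$anchor_nt), v$id)
  j_suffix <- setNames(substr(j$seq_nt, j$anchor_nt + 4L, nchar(j$seq_nt)),
                       j$id)
  template <- paste0(v_prefix[truth$v_id], truth$cdr3_nt,
                     j_suffix[truth$j_id])

  depth <- params$read_depth
  n_junk <- rbinom(1L, depth, params$frac_junk)
  n_clonal <- depth - n_junk
  counts <- as.integer(rmultinom(1L, n_clonal, truth$true_freq))
  clone_of <- rep.int(seq_len(nrow(truth)), counts)
  seqs <- template[clone_of]

  if (params$error_rate > 0) {
    seqs <- vapply(seqs, mutate_bases, character(1),
                   rate = params$error_rate, USE.NAMES = FALSE)
  }
  degraded <- runif(n_clonal) < params$degraded_frac
  quals <- vapply(seq_len(n_clonal), function(i) {
    if (degraded[i]) {
      qual_string(nchar(seqs[i]), 20, 5)
    } else {
      qual_string(nchar(seqs[i]), params$qual_mean, params$qual_sd)
    }
  }, character(1))

  junk_seq <- character(0)
  junk_qual <- character(0)
  if (n_junk > 0) {
    jl <- as.integer(stats::median(nchar(template)))
    junk_seq <- vapply(seq_len(n_junk), function(i) {
      paste(sample(c("A", "C", "G", "T"), jl, replace = TRUE),
            collapse = "")
    }, character(1))
    kind <- rep_len(1:3, n_junk)
    for (i in which(kind == 1L)) { # plant 9 Ns
      pos <- sample.int(jl, 9L)
      s <- strsplit(junk_seq[i], "")[[1]]
      s[pos] <- "N"
      junk_seq[i] <- paste(s, collapse = "")
    }
    junk_qual <- vapply(seq_len(n_junk), function(i) {
      if (kind[i] == 2L) qual_string(jl, 20, 5)
      else qual_string(jl, params$qual_mean, params$qual_sd)
    }, character(1))
  }

  all_seq <- c(seqs, junk_seq)
  all_qual <- c(quals, junk_qual)
  all_clone <- c(truth$clone_id[clone_of], rep(NA_character_, n_junk))
  ord <- sample.int(length(all_seq))
  reads <- tibble(
    read_id = sprintf("read_%06d", seq_along(ord)),
    seq = all_seq[ord],
    qual = all_qual[ord]
  )
  attr(reads, "provenance") <- tibble(read_id = reads$read_id,
                                      clone_id = all_clone[ord])
  if (!is.null(fastq_path)) write_fastq(reads, fastq_path)
  reads
}
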