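#' Annotate reads with V/D/J calls and CDR3 junctions
#'
#' For each read, finds the best-scoring V segment by local alignment, then
#' the best-scoring J segment in the read suffix downstream of the V hit
#' (so `j.read_start >= v.read_end`). Score ties between segments are broken
#' by lexicographically smaller segment id. A read is a no-call when either
#' best score falls below `min_score`; no-call rows keep `NA` calls.
#'
#' The CDR3 junction spans from the read position of the V segment's
#' conserved-cysteine codon (inclusive) through the read position of the J
#' segment's conserved-phenylalanine codon (inclusive) - the C...F junction
#' convention, so a 14-aa CDR3 includes both anchors. If an anchor is not
#' covered by its alignment the read is marked non-productive with a null
#' junction. D segments are assigned by longest exact substring match
#' (>= 5 nt) inside the junction; ties between D segments give `NA`.
#'
#' Only the forward strand is searched by default; set
#' `search_revcomp = TRUE` to also try each read's reverse complement and
#' keep the better-scoring orientation.
#'
#' @param reads Read tibble (columns `read_id`, `seq`; `qual` ignored here).
#' @param ref A `trb_reference` from [load_reference()] / [trb_reference()].
#' @param min_score Minimum alignment score for a V or J call (default 10).
#' @param search_revcomp Also search the reverse complement (default FALSE).
#' @return A tibble with one row per read: `read_id`, `v_call`, `d_call`,
#'   `j_call`, `cdr3_nt`, `cdr3_aa`, `productive`, `v_score`, `j_score`.
#'   The attribute `"annotation_counts"` tallies input, called, and
#'   productive reads.
#' @export
annotate_reads <- function(reads, ref, min_score = 10L,
                           search_revcomp = FALSE) {
  stopifnot(is.data.frame(reads), all(c("read_id", "seq") %in% names(reads)))
  v <- arrange(ref_segments(ref, "V"), id)
  j <- arrange(ref_segments(ref, "J"), id)

  seqs <- reads$seq
  uniq <- unique(seqs)
  hits <- cpp_assign_vj(uniq, v$seq_nt, v$anchor_nt, j$seq_nt, j$anchor_nt,
                        as.integer(min_score))
  if (search_revcomp) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(uniq)
    ))
    hits_rc <- cpp_assign_vj(rc, v$seq_nt, v$anchor_nt, j$seq_nt,
                             j$anchor_nt, as.integer(min_score))
    better <- !is.na(hits_rc$v_score) &
      (is.na(hits$v_score) | hits_rc$v_score > hits$v_score)
    hits[better, ] <- hits_rc[better, ]
    uniq[better] <- rc[better]
  }

  called <- !is.na(hits$v_idx) & !is.na(hits$j_idx)
  cdr3_nt <- rep(NA_character_, length(uniq))
  anchored <- called & !is.na(hits$v_anchor_read) & !is.na(hits$j_anchor_read)
  # junction = [V anchor start, J anchor end): J anchor codon occupies
  # [j_anchor_read, j_anchor_read + 3)
  ok <- anchored & hits$j_anchor_read + 3L <= nchar(uniq) &
    hits$j_anchor_read + 2L >= hits$v_anchor_read
  cdr3_nt[ok] <- substr(uniq[ok], hits$v_anchor_read[ok] + 1L,
                        hits$j_anchor_read[ok] + 3L)
  cdr3_aa <- translate_nt(cdr3_nt)
  productive <- is_productive(cdr3_nt)

  d_call <- rep(NA_character_, length(uniq))
  has_nt <- !is.na(cdr3_nt)
  if (any(has_nt)) {
    d_call[has_nt] <- assign_d(cdr3_nt[has_nt], ref)
  }

  u <- tibble(
    v_call = ifelse(called, v$id[hits$v_idx], NA_character_),
    d_call = ifelse(called, d_call, NA_character_),
    j_call = ifelse(called, j$id[hits$j_idx], NA_character_),
    cdr3_nt = ifelse(called, cdr3_nt, NA_character_),
    cdr3_aa = ifelse(called, cdr3_aa, NA_character_),
    productive = called & productive,
    v_score = hits$v_score,
    j_score = ifelse(called, hits$j_score, NA_integer_)
  )
  idx <- match(seqs, uniq)
  # revcomp may rewrite uniq entries; match on original order instead
  if (search_revcomp) idx <- match(seqs, unique(seqs))
  out <- u[idx, , drop = FALSE]
  out <- mutate(out, read_id = reads$read_id, .before = 1)
  attr(out, "annotation_counts") <- tibble(
    n_input = nrow(out),
    n_called = sum(!is.na(out$v_call) & !is.na(out$j_call)),
    n_productive = sum(out$productive)
  )
  out
}

#' Assign V and J segments to a single read
#'
#' Single-read convenience wrapper around the batch aligner: returns the
#' best V hit and the best J hit constrained to start at or after the V
#' hit's read end, or `NULL` when either best score is below `min_score`.
#'
#' @inheritParams annotate_reads
#' @param read_nt Read nucleotide string.
#' @return A list with elements `v` and `j`, each a one-row tibble
#'   (`segment_id`, `score`, `read_start`, `read_end`, `segment_start`,
#'   `segment_end`), or `NULL` for a no-call.
#' @export
assign_vj <- function(read_nt, ref, min_score = 10L) {
  v <- arrange(ref_segments(ref, "V"), id)
  j <- arrange(ref_segments(ref, "J"), id)
  h <- cpp_assign_vj(read_nt, v$seq_nt, v$anchor_nt, j$seq_nt, j$anchor_nt,
                     as.integer(min_score))
  if (is.na(h$v_idx) || is.na(h$j_idx)) return(NULL)
  list(
    v = tibble(segment_id = v$id[h$v_idx], score = h$v_score,
               read_start = h$v_read_start, read_end = h$v_read_end,
               segment_start = h$v_segment_start,
               segment_end = h$v_segment_end),
    j = tibble(segment_id = j$id[h$j_idx], score = h$j_score,
               read_start = h$j_read_start, read_end = h$j_read_end,
               segment_start = h$j_segment_start,
               segment_end = h$j_segment_end)
  )
}

#' D-segment assignment by longest exact substring match
#'
#' The called D is the segment whose longest exact substring match inside
#' the junction is at least 5 nt and strictly longer than every other D
#' segment's best match; equal best lengths give `NA` (ambiguous), as does
#' no match of length >= 5.
#'
#' @param cdr3_nt Character vector of junction nucleotide strings.
#' @param ref A `trb_reference`.
#' @return Character vector of D segment ids or `NA`.
#' @export
assign_d <- function(cdr3_nt, ref) {
  d <- ref_segments(ref, "D")
  if (nrow(d) == 0) return(rep(NA_character_, length(cdr3_nt)))
  # best (longest) match length per junction x D segment
  best <- matrix(0L, nrow = length(cdr3_nt), ncol = nrow(d))
  for (k in seq_len(nrow(d))) {
    dseq <- d$seq_nt[k]
    dlen <- nchar(dseq)
    for (l in seq(min(dlen, max(nchar(cdr3_nt), 5L)), 5L)) {
      if (l > dlen) next
      todo <- best[, k] == 0L & nchar(cdr3_nt) >= l
      if (!any(todo)) next
      subs <- unique(substring(dseq, 1:(dlen - l + 1L), l:dlen))
      hit <- rep(FALSE, length(cdr3_nt))
      for (s in subs) {
        hit[todo] <- hit[todo] |
          stringr::str_detect(cdr3_nt[todo], stringr::fixed(s))
      }
      best[todo & hit, k] <- l
    }
  }
  top <- apply(best, 1L, max)
  n_at_top <- rowSums(best == top & top > 0L)
  winner <- max.col(best, ties.method = "first")
  out <- ifelse(top >= 5L & n_at_top == 1L, d$id[winner], NA_character_)
  out
}

#' Is a junction productive?
#'
#' A junction is productive when its length is a multiple of 3, its
#' standard-code translation contains no stop codon, and the translation
#' starts with the conserved cysteine (C) and ends with the conserved
#' phenylalanine (F).
#'
#' @param cdr3_nt Character vector of junction nucleotide strings.
#' @return Logical vector (`FALSE` for `NA` input).
#' @examples
#' is_productive(c("TGTGCCAGCTTT", "TGTTAGTTT", "TGTGCCTT"))
#' @export
is_productive <- function(cdr3_nt) {
  aa <- translate_nt(cdr3_nt)
  !is.na(aa) &
    !stringr::str_detect(aa, stringr::fixed("*")) &
    stringr::str_sub(aa, 1, 1) == "C" &
    stringr::str_sub(aa, -1, -1) == "F"
}
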