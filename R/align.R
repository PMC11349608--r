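#' Local alignment of a read against a germline segment
#'
#' Smith-Waterman local alignment with the package's fixed scoring scheme:
#' match +1, mismatch -1, linear gap -2. Among maximal-scoring alignments,
#' ties are broken by smallest `read_start`, then smallest `segment_start`.
#' Coordinates are 0-based, intervals half-open `[start, end)`. A best score
#' of 0 means no positive-scoring local alignment exists ("no hit"); all
#' coordinates are then `NA`.
#'
#' @param read_nt Read nucleotide string.
#' @param segment_nt Segment nucleotide string (or a one-row
#'   `trb_reference` slice, in which case its `seq_nt` is used).
#' @return A one-row tibble: `score`, `read_start`, `read_end`,
#'   `segment_start`, `segment_end`.
#' @examples
#' align_segment("ACGTACGT", "ACGT")
#' @export
align_segment <- function(read_nt, segment_nt) {
  if (is.data.frame(segment_nt)) segment_nt <- segment_nt$seq_nt[1]
  stopifnot(nzchar(read_nt), nzchar(segment_nt))
  h <- cpp_sw_align(read_nt, segment_nt, -1L)
  if (h$score <= 0) {
    return(tibble(score = 0L, read_start = NA_integer_,
                  read_end = NA_integer_, segment_start = NA_integer_,
                  segment_end = NA_integer_))
  }
  tibble(
    score = h$score, read_start = h$read_start, read_end = h$read_end,
    segment_start = h$segment_start, segment_end = h$segment_end
  )
}
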