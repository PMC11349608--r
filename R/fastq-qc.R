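#' Read a Phred+33 FASTQ file
#'
#' Parses a 4-line-per-record FASTQ file into a read tibble. Qualities stay
#' in their compact Phred+33 encoding; use [phred_scores()] to decode a
#' quality string to integer scores.
#'
#' @param path Path to an uncompressed or gzipped FASTQ file.
#' @return A tibble with columns `read_id`, `seq` and `qual` (Phred+33
#'   string), one row per read, in file order.
#' @export
read_fastq <- function(path) {
  tryCatch({
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(
      path, quality.scoring = "phred"
    ))
    if (length(x) == 0) {
      return(tibble(read_id = character(), seq = character(),
                    qual = character()))
    }
    # short quality strings are nul-padded by the parser; the character
    # conversion surfaces them as an error we turn into a record report
    out <- tibble(
      read_id = sub("\\s.*$", "", names(x)),
      seq = as.character(x),
      qual = as.character(Biostrings::quality(x))
    )
    check_reads(out)
    out
  }, error = function(e) {
    abort(paste0("malformed FASTQ '", path, "': ", conditionMessage(e)))
  })
}

#' Write reads to a Phred+33 FASTQ file
#'
#' @param reads Read tibble as returned by [read_fastq()] (columns `read_id`,
#'   `seq`, `qual`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  check_reads(reads)
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id)),
    Biostrings::PhredQuality(reads$qual)
  )
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Decode a Phred+33 quality string to integer scores
#'
#' @param qual Character vector of Phred+33 quality strings.
#' @return A list of integer vectors, one per input string.
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

check_reads <- function(reads) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "seq", "qual") %in% names(reads)))
  bad <- nchar(reads$seq) != nchar(reads$qual)
  if (any(bad)) {
    abort(paste0("sequence/quality length mismatch at record(s): ",
                 paste(head(which(bad), 5), collapse = ", ")))
  }
  invisible(reads)
}

#' Quality-control parameters
#'
#' A read is removed when it contains more than `max_ambiguous` N bases, or
#' when the fraction of positions with Phred quality below `phred_min` is at
#' least `max_low_q_fraction` (the 15% bound is inclusive: a read with
#' exactly 15% low-quality positions is removed). A read failing both rules
#' is tallied under the ambiguous-base counter.
#'
#' @param max_ambiguous Maximum tolerated count of N bases (default 8).
#' @param phred_min Phred score below which a position counts as low quality
#'   (default 30).
#' @param max_low_q_fraction Rejection threshold on the low-quality position
#'   fraction (default 0.15, inclusive).
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(max_ambiguous = 8L, phred_min = 30L,
                      max_low_q_fraction = 0.15) {
  stopifnot(max_ambiguous >= 0, phred_min >= 0,
            max_low_q_fraction >= 0, max_low_q_fraction <= 1)
  structure(
    list(
      max_ambiguous = as.integer(max_ambiguous),
      phred_min = as.integer(phred_min),
      max_low_q_fraction = max_low_q_fraction
    ),
    class = "qc_params"
  )
}

#' Filter reads on ambiguous bases and base quality
#'
#' Applies the two QC rules of [qc_params()], preserving read order. The
#' filter is idempotent: re-filtering kept reads removes nothing.
#'
#' @param reads Read tibble (columns `read_id`, `seq`, `qual`).
#' @param params A [qc_params()] object.
#' @return The kept reads, with a `qc_report` attribute (retrievable via
#'   [qc_report()]): a one-row tibble of `n_raw`, `n_kept`,
#'   `n_removed_ambiguous`, `n_removed_quality`.
#' @export
qc_filter <- function(reads, params = qc_params()) {
  check_reads(reads)
  n_raw <- nrow(reads)
  if (n_raw == 0) {
    out <- reads
    report <- tibble(n_raw = 0L, n_kept = 0L, n_removed_ambiguous = 0L,
                     n_removed_quality = 0L)
    attr(out, "qc_report") <- report
    return(out)
  }
  n_amb <- stringr::str_count(reads$seq, stringr::fixed("N"))
  fail_amb <- n_amb > params$max_ambiguous
  low_frac <- vapply(reads$qual, function(q) {
    s <- utf8ToInt(q) - 33L
    mean(s < params$phred_min)
  }, numeric(1), USE.NAMES = FALSE)
  fail_qual <- low_frac >= params$max_low_q_fraction
  keep <- !fail_amb & !fail_qual
  out <- reads[keep, , drop = FALSE]
  report <- tibble(
    n_raw = n_raw,
    n_kept = sum(keep),
    n_removed_ambiguous = sum(fail_amb),
    n_removed_quality = sum(fail_qual & !fail_amb)
  )
  attr(out, "qc_report") <- report
  out
}

#' @rdname qc_filter
#' @param x A tibble returned by [qc_filter()].
#' @export
qc_report <- function(x) {
  rep <- attr(x, "qc_report")
  if (is.null(rep)) abort("object carries no qc_report attribute")
  rep
}
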