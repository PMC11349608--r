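# AIRR-style Rearrangement TSV input/output for annotation and clonotype
# tables. Mandatory columns follow the Rearrangement schema subset used
# throughout the package; booleans are written as "T"/"F".

airr_columns <- c(
  "sequence_id", "v_call", "d_call", "j_call", "junction", "junction_aa",
  "productive", "duplicate_count", "frequency"
)

#' Write a clonotype or annotation table as AIRR-style TSV
#'
#' Accepts either a [build_repertoire()] clonotype table (columns `cdr3_aa`,
#' `v_call`, `j_call`, `count`, `frequency`, optionally `d_call`, `cdr3_nt`)
#' or an [annotate_reads()] table, and writes the AIRR Rearrangement column
#' subset `sequence_id, v_call, d_call, j_call, junction, junction_aa,
#' productive, duplicate_count, frequency`.
#'
#' @param x Clonotype or annotation tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(x, path) {
  if (all(c("cdr3_aa", "count", "frequency") %in% names(x))) {
    out <- tibble(
      sequence_id = sprintf("clonotype_%d", seq_len(nrow(x))),
      v_call = x$v_call,
      d_call = if ("d_call" %in% names(x)) x$d_call else NA_character_,
      j_call = x$j_call,
      junction = if ("cdr3_nt" %in% names(x)) x$cdr3_nt else NA_character_,
      junction_aa = x$cdr3_aa,
      productive = TRUE,
      duplicate_count = as.integer(x$count),
      frequency = x$frequency
    )
  } else if ("read_id" %in% names(x)) {
    out <- tibble(
      sequence_id = x$read_id,
      v_call = x$v_call,
      d_call = x$d_call,
      j_call = x$j_call,
      junction = x$cdr3_nt,
      junction_aa = x$cdr3_aa,
      productive = x$productive,
      duplicate_count = 1L,
      frequency = NA_real_
    )
  } else {
    abort("x is neither a clonotype table nor an annotation table")
  }
  out$productive <- ifelse(out$productive, "T", "F")
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Read an AIRR-style TSV written by [write_airr()]
#'
#' @param path Path to the TSV.
#' @return A tibble with the AIRR column subset; `productive` decoded to
#'   logical, empty strings to `NA`.
#' @export
read_airr <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    sequence_id = readr::col_character(),
    v_call = readr::col_character(),
    d_call = readr::col_character(),
    j_call = readr::col_character(),
    junction = readr::col_character(),
    junction_aa = readr::col_character(),
    productive = readr::col_character(),
    duplicate_count = readr::col_integer(),
    frequency = readr::col_double()
  ), na = "")
  missing <- setdiff(airr_columns, names(x))
  if (length(missing) > 0) {
    abort(paste0("AIRR table lacks mandatory column(s): ",
                 paste(missing, collapse = ", ")))
  }
  x$productive <- x$productive == "T"
  x[airr_columns]
}

# rebuild a trb_repertoire from an AIRR clonotype TSV plus sample metadata
repertoire_from_airr <- function(path, sample_id, group, clinical = NULL) {
  x <- read_airr(path)
  tab <- tibble(
    cdr3_aa = x$junction_aa,
    v_call = x$v_call,
    j_call = x$j_call,
    d_call = x$d_call,
    cdr3_nt = x$junction,
    count = x$duplicate_count,
    frequency = x$frequency
  )
  new_repertoire(tab, sample_id = sample_id, group = group,
                 clinical = clinical)
}
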