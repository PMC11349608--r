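#' Load a germline V/D/J segment reference
#'
#' Reads a multi-FASTA of germline TRB segment sequences together with a
#' tab-separated anchor table (columns `id`, `kind`, `anchor_nt`) and returns
#' a validated reference tibble. The anchor is the 0-based offset of the first
#' base of the conserved anchor codon: the second cysteine (C) for V segments
#' and the conserved phenylalanine (F) for J segments; D segments carry no
#' anchor. All coordinates in the package are 0-based and intervals are
#' half-open `[start, end)`.
#'
#' @param fasta_path Path to the segment FASTA.
#' @param anchor_table_path Path to the anchor table TSV.
#' @return A tibble of class `trb_reference` with columns `id`, `kind`
#'   (`"V"`, `"D"` or `"J"`), `seq_nt`, `anchor_nt` (integer, `NA` for D) and
#'   `family` (id truncated after the family number, e.g. `TRBV7-6` ->
#'   `TRBV7`).
#' @examples
#' ref <- trb_reference()
#' dplyr::count(ref, kind)
#' @export
load_reference <- function(fasta_path, anchor_table_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  anchors <- readr::read_tsv(anchor_table_path,
    col_types = readr::cols(
      id = readr::col_character(),
      kind = readr::col_character(),
      anchor_nt = readr::col_integer()
    )
  )
  ids <- names(seqs)
  if (anyDuplicated(ids)) {
    abort("duplicate segment ids in reference FASTA")
  }
  if (!setequal(ids, anchors$id)) {
    abort("FASTA ids and anchor-table ids do not match")
  }
  ref <- anchors %>%
    mutate(seq_nt = unname(as.character(seqs[id]))) %>%
    select(id, kind, seq_nt, anchor_nt) %>%
    mutate(family = family_of(id))
  validate_reference(ref)
  structure(arrange(ref, kind, id), class = c("trb_reference", class(ref)))
}

#' Bundled synthetic TRB germline reference
#'
#' A synthetic-but-realistically-named germline segment set shipped with the
#' package: 58 V segments grouped into 28 families (the TRBV7 family holds 8
#' subfamilies), 2 D segments, and 14 J segments including the
#' pseudogene-style `TRBJ2-2p`. Sequences are short synthetic amplicon-scale
#' segments (V ~60 nt ending shortly after the conserved Cys codon, J ~48 nt
#' starting shortly before the conserved Phe codon); they are not IMGT allele
#' sequences.
#'
#' @return A `trb_reference` tibble (see [load_reference()]).
#' @export
trb_reference <- function() {
  load_reference(
    system.file("extdata", "trb_synthetic_reference.fasta",
      package = "tcrbrep", mustWork = TRUE
    ),
    system.file("extdata", "trb_synthetic_anchors.tsv",
      package = "tcrbrep", mustWork = TRUE
    )
  )
}

validate_reference <- function(ref) {
  stopifnot(all(ref$kind %in% c("V", "D", "J")))
  for (k in c("V", "J")) {
    if (!any(ref$kind == k)) abort(paste0("reference has no ", k, " segments"))
  }
  vj <- ref[ref$kind %in% c("V", "J"), ]
  if (anyNA(vj$anchor_nt)) {
    bad <- vj$id[is.na(vj$anchor_nt)]
    abort(paste0("missing anchor for segment(s): ", paste(bad, collapse = ", ")))
  }
  if (any(vj$anchor_nt + 3L > nchar(vj$seq_nt))) {
    bad <- vj$id[vj$anchor_nt + 3L > nchar(vj$seq_nt)]
    abort(paste0("anchor codon extends past sequence end: ",
                 paste(bad, collapse = ", ")))
  }
  codon <- substr(vj$seq_nt, vj$anchor_nt + 1L, vj$anchor_nt + 3L)
  aa <- translate_nt(codon)
  want <- ifelse(vj$kind == "V", "C", "F")
  if (any(aa != want)) {
    bad <- vj$id[aa != want]
    abort(paste0(
      "anchor codon does not encode the conserved residue (C for V, F for J): ",
      paste(bad, collapse = ", ")
    ))
  }
  invisible(ref)
}

#' Gene family of a segment id
#'
#' Truncates an IMGT-style segment id after its family number, collapsing
#' subfamily suffixes: `TRBV7-6 -> TRBV7`, `TRBJ2-2p -> TRBJ2`, `TRBV16 ->
#' TRBV16`. The function is a projection: applying it to a family name
#' returns the name unchanged.
#'
#' @param segment_id Character vector of segment or family ids.
#' @return Character vector of family names.
#' @examples
#' family_of(c("TRBV7-6", "TRBV16", "TRBJ2-2p"))
#' @export
family_of <- function(segment_id) {
  ok <- grepl("^[A-Z]+[0-9]+(-.+)?$", segment_id)
  if (!all(ok)) {
    abort(paste0("unparseable segment id(s): ",
                 paste(unique(segment_id[!ok]), collapse = ", ")))
  }
  sub("-.*$", "", segment_id)
}

#' Collapse a segment-level usage vector to gene families
#'
#' Sums usage values over segments sharing a family; the total is conserved.
#'
#' @param usage Named numeric vector (or named list coercible to one) of
#'   nonnegative usage values keyed by segment id.
#' @return Named numeric vector keyed by family name, in first-appearance
#'   order of the families.
#' @examples
#' collapse_families(c("TRBV7-2" = 0.1, "TRBV7-6" = 0.2, "TRBV16" = 0.05))
#' @export
collapse_families <- function(usage) {
  usage <- unlist(usage)
  if (length(usage) == 0) {
    return(setNames(numeric(0), character(0)))
  }
  if (is.null(names(usage)) || any(!nzchar(names(usage)))) {
    abort("usage must be a named vector keyed by segment id")
  }
  if (any(usage < 0)) abort("usage values must be nonnegative")
  fam <- family_of(names(usage))
  out <- vapply(split(usage, factor(fam, levels = unique(fam))), sum,
                numeric(1))
  out
}

ref_segments <- function(ref, what) {
  ref[ref$kind == what, , drop = FALSE]
}
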