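new_repertoire <- function(tab, sample_id, group, clinical = NULL) {
  total <- sum(tab$count)
  structure(
    as_tibble(tab),
    sample_id = sample_id,
    group = group,
    clinical = clinical,
    total_productive_reads = total,
    class = c("trb_repertoire", class(as_tibble(tab)))
  )
}

#' Assemble a clonotype table from read annotations
#'
#' Keeps productive annotations only and groups them by the clonotype key
#' `(cdr3_aa, v_call, j_call)`. `count` is the number of reads in the group
#' and `frequency = count / total productive reads`. The representative
#' `cdr3_nt` is the most frequent nucleotide variant in the group; `d_call`
#' is the modal D call (ties or all-`NA` give `NA`).
#'
#' @param annotations Annotation tibble from [annotate_reads()].
#' @param sample_id Sample identifier string.
#' @param group Group label, `"tumor"` or `"normal"`.
#' @param clinical Optional named list of clinical covariates
#'   (e.g. `list(LDH = 210, NLR = 2.6, ALC = 1.2)`).
#' @return A `trb_repertoire`: a tibble of clonotypes (`cdr3_aa`, `v_call`,
#'   `j_call`, `d_call`, `cdr3_nt`, `count`, `frequency`) sorted by
#'   decreasing count, with `sample_id`, `group`, `clinical` and
#'   `total_productive_reads` attributes. Zero productive annotations give
#'   an empty repertoire.
#' @export
build_repertoire <- function(annotations, sample_id, group = c("tumor", "normal"),
                             clinical = NULL) {
  group <- arg_match(group)
  prod <- filter(annotations, productive)
  if (nrow(prod) == 0) {
    tab <- tibble(cdr3_aa = character(), v_call = character(),
                  j_call = character(), d_call = character(),
                  cdr3_nt = character(), count = integer(),
                  frequency = numeric())
    return(new_repertoire(tab, sample_id, group, clinical))
  }
  modal <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_character_)
    tt <- sort(table(x), decreasing = TRUE)
    if (length(tt) > 1 && tt[1] == tt[2]) return(NA_character_)
    names(tt)[1]
  }
  tab <- prod %>%
    group_by(cdr3_aa, v_call, j_call) %>%
    summarise(
      d_call = modal(d_call),
      cdr3_nt = names(sort(table(cdr3_nt), decreasing = TRUE))[1],
      count = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(frequency = count / sum(count)) %>%
    arrange(desc(count), cdr3_aa, v_call, j_call)
  new_repertoire(tab, sample_id, group, clinical)
}

#' @export
print.trb_repertoire <- function(x, ...) {
  cat(sprintf(
    "TRB repertoire '%s' (%s): %d clonotypes, %d productive reads\n",
    attr(x, "sample_id") %||% "?", attr(x, "group") %||% "?",
    nrow(x), attr(x, "total_productive_reads") %||% 0L
  ))
  NextMethod()
}

# unique-CDR3aa frequency vector of a repertoire (diversity convention:
# V/J calls are collapsed, counts summed per unique amino-acid junction)
cdr3_frequencies <- function(repertoire) {
  if (nrow(repertoire) == 0) return(numeric(0))
  counts <- vapply(split(repertoire$count, repertoire$cdr3_aa), sum,
                   numeric(1))
  unname(counts / sum(counts))
}
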