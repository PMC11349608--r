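#' Repertoire diversity indices
#'
#' Closed-form diversity statistics over a clonotype frequency vector, using
#' the standard repertoire conventions: Shannon entropy in natural log
#' (nats), clonality as the normalized-entropy complement `1 - H/ln(R)`,
#' Simpson as the dominance form `sum(p^2)`, CF100 as the cumulative
#' frequency of the 100 most abundant clonotypes, and D50 as `k/R` where `k`
#' is the smallest number of most-abundant clonotypes whose cumulative
#' frequency reaches 0.5.
#'
#' @param freqs Numeric vector of clonotype frequencies. For
#'   [shannon_entropy()], [clonality()] and [simpson_index()] it must sum
#'   to 1 (within 1e-6) with all entries > 0.
#' @return A single numeric value.
#' @examples
#' shannon_entropy(rep(0.25, 4)) # ln 4
#' clonality(rep(0.1, 10)) # 0: perfectly even
#' simpson_index(rep(0.1, 10)) # 1/10
#' d50(rep(0.1, 10)) # 0.5
#' @name diversity_indices
NULL

check_freqs <- function(freqs, strict = TRUE) {
  if (length(freqs) == 0) abort("empty frequency vector")
  if (strict) {
    if (any(freqs <= 0)) abort("frequencies must be positive")
    if (abs(sum(freqs) - 1) > 1e-6) abort("frequencies must sum to 1")
  }
  invisible(freqs)
}

#' @rdname diversity_indices
#' @export
shannon_entropy <- function(freqs) {
  check_freqs(freqs)
  -sum(freqs * log(freqs))
}

#' @rdname diversity_indices
#' @export
clonality <- function(freqs) {
  check_freqs(freqs)
  r <- length(freqs)
  if (r < 2) abort("clonality undefined for a single clonotype")
  1 - shannon_entropy(freqs) / log(r)
}

#' @rdname diversity_indices
#' @export
simpson_index <- function(freqs) {
  check_freqs(freqs)
  sum(freqs^2)
}

#' @rdname diversity_indices
#' @export
cf100 <- function(freqs) {
  check_freqs(freqs, strict = FALSE)
  sum(sort(freqs, decreasing = TRUE)[seq_len(min(100L, length(freqs)))])
}

#' @rdname diversity_indices
#' @export
d50 <- function(freqs) {
  check_freqs(freqs, strict = FALSE)
  p <- sort(freqs, decreasing = TRUE) / sum(freqs)
  k <- which(cumsum(p) >= 0.5)[1]
  k / length(p)
}

#' Per-sample diversity profile
#'
#' Computes the full per-sample statistic vector: diversity indices over
#' unique-CDR3aa frequencies (V/J calls collapsed), clonotype and gene-space
#' counts, and the mean CDR3 amino-acid length. `n_vdj_combos` counts
#' distinct `(v_call, d_call, j_call)` triples with an unassigned D treated
#' as its own class.
#'
#' @param repertoire A `trb_repertoire`.
#' @return A one-row tibble: `sample_id`, `group`, `shannon_entropy`,
#'   `clonality`, `simpson`, `cf100`, `d50`, `n_clonotypes`,
#'   `n_v_segments`, `n_vj_pairs`, `n_vdj_combos`, `mean_cdr3_len`,
#'   `total_productive_reads`. An empty repertoire yields zero counts and
#'   `NA` indices.
#' @export
diversity_profile <- function(repertoire) {
  base <- tibble(
    sample_id = attr(repertoire, "sample_id") %||% NA_character_,
    group = attr(repertoire, "group") %||% NA_character_
  )
  if (nrow(repertoire) == 0) {
    return(mutate(base,
      shannon_entropy = NA_real_, clonality = NA_real_, simpson = NA_real_,
      cf100 = NA_real_, d50 = NA_real_, n_clonotypes = 0L,
      n_v_segments = 0L, n_vj_pairs = 0L, n_vdj_combos = 0L,
      mean_cdr3_len = NA_real_, total_productive_reads = 0L
    ))
  }
  p <- cdr3_frequencies(repertoire)
  mutate(base,
    shannon_entropy = shannon_entropy(p),
    clonality = if (length(p) >= 2) clonality(p) else NA_real_,
    simpson = simpson_index(p),
    cf100 = cf100(p),
    d50 = d50(p),
    n_clonotypes = length(p),
    n_v_segments = dplyr::n_distinct(repertoire$v_call),
    n_vj_pairs = nrow(distinct(repertoire, v_call, j_call)),
    n_vdj_combos = nrow(distinct(
      mutate(repertoire, d_call = ifelse(is.na(d_call), "none", d_call)),
      v_call, d_call, j_call
    )),
    mean_cdr3_len = mean(nchar(repertoire$cdr3_aa)),
    total_productive_reads = attr(repertoire, "total_productive_reads")
  )
}
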