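#' CDR3 amino-acid length distribution
#'
#' Histogram of CDR3 lengths with moment estimates and a goodness-of-fit
#' score against a Gaussian: `gaussian_fit_r2` is the coefficient of
#' determination between the observed length proportions and the
#' discretized `Normal(mean, sd)` probability mass (integrated over
#' half-integer bin edges and renormalized over the observed support).
#' Weighting is by unique clonotype by default; `by_read` weights each
#' length by its read count.
#'
#' @param repertoire A nonempty `trb_repertoire`.
#' @param weighting `"by_clonotype"` (default) or `"by_read"`.
#' @return A list of class `trb_lengthdist`: `histogram` (tibble `len`,
#'   `n`, `prop`), `mean`, `sd`, `gaussian_fit_r2`, `weighting`.
#' @export
length_distribution <- function(repertoire,
                                weighting = c("by_clonotype", "by_read")) {
  weighting <- arg_match(weighting)
  if (nrow(repertoire) == 0) abort("empty repertoire")
  len <- nchar(repertoire$cdr3_aa)
  w <- if (weighting == "by_read") repertoire$count else rep(1L, nrow(repertoire))
  n_by_len <- vapply(split(w, len), sum, numeric(1))
  lens <- as.integer(names(n_by_len))
  prop <- unname(n_by_len) / sum(n_by_len)
  mu <- sum(lens * prop)
  sigma <- sqrt(sum(prop * (lens - mu)^2))
  r2 <- NA_real_
  if (sigma > 0 && length(lens) > 1) {
    pmf <- pnorm(lens + 0.5, mu, sigma) - pnorm(lens - 0.5, mu, sigma)
    pmf <- pmf / sum(pmf)
    ss_res <- sum((prop - pmf)^2)
    ss_tot <- sum((prop - mean(prop))^2)
    r2 <- 1 - ss_res / ss_tot
  }
  structure(
    list(
      histogram = tibble(len = lens, n = unname(n_by_len), prop = prop),
      mean = mu, sd = sigma, gaussian_fit_r2 = r2, weighting = weighting
    ),
    class = "trb_lengthdist"
  )
}

#' Clonotype counts by frequency region
#'
#' Bins clonotype frequencies into half-open decade regions `(lo, hi]`. The
#' default edges `0, 1e-5, 1e-4, 1e-3, 1e-2, 1` include the 0.01%-0.1%
#' region (`(1e-4, 1e-3]`) in which tumor and normal repertoires are
#' typically compared.
#'
#' @param freqs Clonotype frequency vector, all values in `(0, 1]`.
#' @param edges Strictly increasing breakpoints spanning `(0, 1]`.
#' @return A tibble with columns `region` (label `"(lo, hi]"`), `lo`, `hi`
#'   and `n`; counts sum to `length(freqs)`.
#' @export
frequency_regions <- function(freqs,
                              edges = c(0, 1e-5, 1e-4, 1e-3, 1e-2, 1)) {
  if (length(freqs) == 0) abort("empty frequency vector")
  if (any(freqs <= 0 | freqs > 1)) abort("frequencies must lie in (0, 1]")
  if (any(diff(edges) <= 0) || edges[1] != 0 || edges[length(edges)] < 1) {
    abort("edges must be strictly increasing and span (0, 1]")
  }
  bin <- cut(freqs, breaks = edges, right = TRUE, include.lowest = FALSE)
  counts <- as.integer(table(bin))
  tibble(
    region = levels(bin),
    lo = edges[-length(edges)],
    hi = edges[-1],
    n = counts
  )
}

#' V-J gene-usage matrix of a repertoire
#'
#' Read-weighted usage of every V x J call pair over the reference gene
#' space (58 x 14 = 812 cells for the bundled reference). Cell `(v, j)` is
#' the fraction of productive reads carrying that call pair; marginals are
#' the row and column sums.
#'
#' @param repertoire A `trb_repertoire`.
#' @param ref The `trb_reference` defining the gene space.
#' @return A list of class `trb_usage`: `matrix` (V rows x J columns),
#'   `v_usage` and `j_usage` (named marginal vectors), `n_vj_pairs`
#'   (nonzero cells), `sample_id`.
#' @export
vj_usage <- function(repertoire, ref) {
  v_ids <- sort(ref_segments(ref, "V")$id)
  j_ids <- sort(ref_segments(ref, "J")$id)
  m <- matrix(0, nrow = length(v_ids), ncol = length(j_ids),
              dimnames = list(v_ids, j_ids))
  if (nrow(repertoire) > 0) {
    if (!all(repertoire$v_call %in% v_ids)) {
      abort("repertoire contains V calls outside the reference")
    }
    if (!all(repertoire$j_call %in% j_ids)) {
      abort("repertoire contains J calls outside the reference")
    }
    counts <- repertoire %>%
      group_by(v_call, j_call) %>%
      summarise(count = sum(count), .groups = "drop")
    m[cbind(counts$v_call, counts$j_call)] <- counts$count
    m <- m / sum(m)
  }
  structure(
    list(
      matrix = m,
      v_usage = rowSums(m),
      j_usage = colSums(m),
      n_vj_pairs = sum(m > 0),
      sample_id = attr(repertoire, "sample_id") %||% NA_character_
    ),
    class = "trb_usage"
  )
}

#' @export
print.trb_usage <- function(x, ...) {
  cat(sprintf(
    "V-J usage matrix (%d x %d = %d cells, %d nonzero) for sample '%s'\n",
    nrow(x$matrix), ncol(x$matrix), length(x$matrix), x$n_vj_pairs,
    x$sample_id
  ))
  invisible(x)
}

#' CDR3 overlap rate between two repertoires
#'
#' Overlap coefficient on unique CDR3aa sets:
#' `|A intersect B| / min(|A|, |B|)`. Nested repertoires therefore score 1.
#'
#' @param rep_a,rep_b Nonempty `trb_repertoire` objects.
#' @return Overlap rate in `[0, 1]`.
#' @export
overlap_rate <- function(rep_a, rep_b) {
  a <- unique(rep_a$cdr3_aa)
  b <- unique(rep_b$cdr3_aa)
  if (length(a) == 0 || length(b) == 0) abort("empty repertoire")
  length(intersect(a, b)) / min(length(a), length(b))
}
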