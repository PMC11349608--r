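#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Mann-Whitney result
#'
#' @param x A `trb_mw` object.
#' @param ... Unused.
#' @return A one-row tibble of descriptive statistics, `u_statistic`,
#'   `p_value` and `method`.
#' @export
tidy.trb_mw <- function(x, ...) tidy_mw(x)

#' @rdname tidy.trb_mw
#' @export
glance.trb_mw <- function(x, ...) {
  tibble(u_statistic = x$u_statistic, p_value = x$p_value,
         method = x$method)
}

#' Tidy a Spearman correlation result
#'
#' @param x A `trb_cor` object.
#' @param ... Unused.
#' @export
tidy.trb_cor <- function(x, ...) {
  tibble(rho = x$rho, p_value = x$p_value, n = x$n)
}

#' Tidy a V-J usage matrix into long format
#'
#' @param x A `trb_usage` object.
#' @param ... Unused.
#' @return A tibble `v_call`, `j_call`, `frequency` (heatmap-ready).
#' @export
tidy.trb_usage <- function(x, ...) tidy_usage(x)

tidy_usage <- function(x) {
  m <- x$matrix
  tibble(
    v_call = rep(rownames(m), times = ncol(m)),
    j_call = rep(colnames(m), each = nrow(m)),
    frequency = as.vector(m)
  )
}

#' Tidy a J-family clustering
#'
#' @param x A `trb_jclust` object.
#' @param ... Unused.
#' @return A tibble `j_call`, `cluster`, in dendrogram order.
#' @export
tidy.trb_jclust <- function(x, ...) {
  tibble(j_call = x$order, cluster = unname(x$clusters[x$order]))
}

#' Tidy a CDR3 length distribution
#'
#' @param x A `trb_lengthdist` object.
#' @param ... Unused.
#' @export
tidy.trb_lengthdist <- function(x, ...) x$histogram

#' @rdname tidy.trb_lengthdist
#' @export
glance.trb_lengthdist <- function(x, ...) {
  tibble(mean = x$mean, sd = x$sd, gaussian_fit_r2 = x$gaussian_fit_r2,
         weighting = x$weighting)
}
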