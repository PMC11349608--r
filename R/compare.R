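#' Mann-Whitney U test
#'
#' Rank-sum test with midranks for ties. `U` is computed from the rank sum
#' of `x`. The two-sided p-value is exact (full enumeration of all
#' `choose(nx + ny, nx)` group labelings of the pooled values) when
#' `nx + ny <= exact_max` and the pooled sample has no ties; otherwise the
#' normal approximation with tie correction and a 0.5 continuity correction
#' is used.
#'
#' @param x,y Nonempty numeric samples.
#' @param exact_max Combined sample size at or below which the exact
#'   enumeration path is used (default 12).
#' @return An object of class `trb_mw` with fields `u_statistic`,
#'   `p_value`, `method` (`"exact"` or `"normal"`), `mean_a`, `sd_a`,
#'   `mean_b`, `sd_b`, `n_a`, `n_b`. [generics::tidy()] gives a one-row
#'   tibble.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4)) # exact p = 1/3
#' @export
mann_whitney_u <- function(x, y, exact_max = 12L) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be nonempty")
  nx <- length(x)
  ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(pooled))
  mu <- nx * ny / 2
  if (nx + ny <= exact_max && !ties) {
    combos <- utils::combn(nx + ny, nx)
    u_all <- colSums(matrix(r[combos], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-12)
    method <- "exact"
  } else {
    n <- nx + ny
    tie_tab <- table(pooled)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal"
  }
  structure(
    list(
      u_statistic = u, p_value = p, method = method,
      mean_a = mean(x), sd_a = sd(x), mean_b = mean(y), sd_b = sd(y),
      n_a = nx, n_b = ny
    ),
    class = "trb_mw"
  )
}

#' @export
print.trb_mw <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (%s), two-sided p = %.6g [n = %d vs %d]\n",
              x$u_statistic, x$method, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks, with a two-sided p-value from the
#' t-distribution approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return An object of class `trb_cor` with fields `rho`, `p_value`, `n`.
#' @examples
#' spearman_cor(1:5, c(1, 3, 2, 5, 4)) # rho = 0.8
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 3) abort("need at least 3 pairs")
  if (anyNA(x) || anyNA(y)) abort("missing values in correlation input")
  rx <- rank(x)
  ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0) {
    abort("correlation undefined: zero rank variance")
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tt), df = n - 2)
  }
  structure(list(rho = rho, p_value = p, n = n), class = "trb_cor")
}

#' @export
print.trb_cor <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f, two-sided p = %.6g [n = %d]\n",
              x$rho, x$p_value, x$n))
  invisible(x)
}

#' Compare a diversity metric between two groups
#'
#' Applies [mann_whitney_u()] to the per-sample values of one
#' [diversity_profile()] column, tumor group first.
#'
#' @param profiles Tibble of per-sample diversity profiles (one row per
#'   sample) with a `group` column.
#' @param metric Name of the profile column to compare.
#' @param groups Length-2 character vector naming the two groups
#'   (first = "a" side of the test).
#' @return A one-row tibble: `metric`, descriptive stats per group,
#'   `u_statistic`, `p_value`.
#' @export
compare_diversity <- function(profiles, metric,
                              groups = c("tumor", "normal")) {
  if (!metric %in% names(profiles)) {
    abort(paste0("unknown metric: ", metric))
  }
  a <- profiles[[metric]][profiles$group == groups[1]]
  b <- profiles[[metric]][profiles$group == groups[2]]
  mw <- mann_whitney_u(a, b)
  mutate(tidy_mw(mw), metric = metric, .before = 1)
}

tidy_mw <- function(mw) {
  tibble(
    mean_a = mw$mean_a, sd_a = mw$sd_a, n_a = mw$n_a,
    mean_b = mw$mean_b, sd_b = mw$sd_b, n_b = mw$n_b,
    u_statistic = mw$u_statistic, p_value = mw$p_value, method = mw$method
  )
}

#' Per-sample gene usage in long format
#'
#' Expands a list of repertoires into a per-sample usage table over the full
#' reference gene space (zero-usage genes included), at every comparison
#' level.
#'
#' @param repertoires List of `trb_repertoire` objects.
#' @param ref The `trb_reference`.
#' @return A tibble: `sample_id`, `group`, `level` (`v_subfamily`,
#'   `v_family`, `j`, `vj_pair`), `gene`, `frequency`.
#' @export
usage_by_sample <- function(repertoires, ref) {
  purrr::map_dfr(repertoires, function(rep) {
    u <- vj_usage(rep, ref)
    vs <- u$v_usage
    vf <- collapse_families(vs)
    js <- u$j_usage
    vj <- as.vector(u$matrix)
    vj_names <- as.vector(outer(rownames(u$matrix), colnames(u$matrix),
                                paste, sep = "/"))
    tibble(
      sample_id = attr(rep, "sample_id"),
      group = attr(rep, "group"),
      level = c(rep("v_subfamily", length(vs)), rep("v_family", length(vf)),
                rep("j", length(js)), rep("vj_pair", length(vj))),
      gene = c(names(vs), names(vf), names(js), vj_names),
      frequency = c(unname(vs), unname(vf), unname(js), vj)
    )
  })
}

#' Tumor-vs-normal usage comparison at a chosen level
#'
#' One Mann-Whitney test per gene, family, or V/J pair in the reference
#' space, on per-sample usage frequencies. Both the raw p-value and the
#' Benjamini-Hochberg adjusted value are reported; the `significant` flag
#' uses raw `p < alpha` (the convention of the source analyses), with the
#' BH column alongside for multiplicity-aware reading.
#'
#' @param usage Long usage table from [usage_by_sample()].
#' @param level One of `"v_subfamily"`, `"v_family"`, `"j"`, `"vj_pair"`.
#' @param groups Length-2 character vector of group labels (first = "a").
#' @param alpha Raw-p significance threshold (default 0.05).
#' @return A tibble with one row per gene: descriptive stats,
#'   `u_statistic`, `p_value`, `p_adjusted`, `significant`, sorted by
#'   `p_value`.
#' @export
compare_usage <- function(usage, level = c("v_subfamily", "v_family", "j",
                                           "vj_pair"),
                          groups = c("tumor", "normal"), alpha = 0.05) {
  level <- arg_match(level)
  u <- filter(usage, level == !!level)
  if (nrow(u) == 0) abort("no usage rows at the requested level")
  res <- u %>%
    group_by(gene) %>%
    dplyr::group_modify(function(d, key) {
      a <- d$frequency[d$group == groups[1]]
      b <- d$frequency[d$group == groups[2]]
      tidy_mw(mann_whitney_u(a, b))
    }) %>%
    ungroup() %>%
    mutate(
      level = level,
      p_adjusted = p.adjust(p_value, method = "BH"),
      significant = p_value < alpha
    ) %>%
    arrange(p_value, gene)
  res
}

#' Correlate a diversity metric with a clinical covariate
#'
#' Spearman correlation between per-sample diversity and a clinical
#' covariate, computed separately within each group.
#'
#' @param profiles Per-sample profile tibble with `group`, the metric
#'   column, and the covariate column.
#' @param metric Diversity column name (default `"shannon_entropy"`, the
#'   convention for "TCR diversity").
#' @param covariate Clinical covariate column name (e.g. `"LDH"`, `"NLR"`,
#'   `"ALC"`).
#' @return A tibble with one row per group: `group`, `metric`, `covariate`,
#'   `rho`, `p_value`, `n`.
#' @export
correlate_clinical <- function(profiles, metric = "shannon_entropy",
                               covariate) {
  if (!covariate %in% names(profiles)) {
    abort(paste0("missing covariate column: ", covariate))
  }
  if (!metric %in% names(profiles)) {
    abort(paste0("unknown metric: ", metric))
  }
  miss <- is.na(profiles[[covariate]])
  if (any(miss)) {
    abort(paste0("covariate '", covariate, "' missing for sample(s): ",
                 paste(profiles$sample_id[miss], collapse = ", ")))
  }
  purrr::map_dfr(unique(profiles$group), function(g) {
    d <- profiles[profiles$group == g, ]
    ct <- spearman_cor(d[[metric]], d[[covariate]])
    tibble(group = g, metric = metric, covariate = covariate,
           rho = ct$rho, p_value = ct$p_value, n = ct$n)
  })
}

#' Cluster J families by their V-usage columns
#'
#' Agglomerative clustering (Euclidean distance, average linkage) of the J
#' columns of a group-mean V x J usage matrix, cut into the two top-level
#' clusters. `stats::hclust` resolves distance ties deterministically by
#' column index order.
#'
#' @param mean_usage A V x J matrix (e.g. the mean of per-sample
#'   `vj_usage()$matrix` within a group).
#' @return A list of class `trb_jclust`: `order` (J ids in dendrogram
#'   order), `clusters` (named 1/2 membership), `merge` (hclust merge
#'   matrix), `newick` (dendrogram string), `hclust`.
#' @export
cluster_j_families <- function(mean_usage) {
  stopifnot(is.matrix(mean_usage), ncol(mean_usage) >= 2)
  d <- dist(t(mean_usage), method = "euclidean")
  hc <- hclust(d, method = "average")
  cl <- cutree(hc, k = 2)
  phylo <- ape::as.phylo(hc)
  structure(
    list(
      order = colnames(mean_usage)[hc$order],
      clusters = cl,
      merge = hc$merge,
      newick = ape::write.tree(phylo),
      hclust = hc
    ),
    class = "trb_jclust"
  )
}

#' @export
print.trb_jclust <- function(x, ...) {
  cat("J-family clustering (Euclidean, average linkage)\n")
  for (k in 1:2) {
    cat(sprintf("  C%d: %s\n", k,
                paste(names(x$clusters)[x$clusters == k], collapse = ", ")))
  }
  invisible(x)
}
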