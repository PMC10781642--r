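#' Brain and body proportions at birth
#'
#' The classic altriciality metrics: neonatal brain mass as a fraction of
#' adult brain mass, and neonatal body mass as a fraction of maternal body
#' mass. Stored as fractions in \[0, 1\]; multiply by 100 only at the
#' reporting layer. Fractions above 1 are permitted (they occur in real
#' compilations) but flagged with a warning.
#'
#' @param table a species table (see [read_species_table()]).
#' @return a tibble with `species`, `clade`, `brain_prop`, `body_prop`.
#' @export
compute_proportions <- function(table) {
  if (any(table$adult_brain <= 0) || any(table$maternal_body <= 0)) {
    abort("adult brain and maternal body masses must be > 0")
  }
  out <- tibble(
    species = table$species,
    clade = table$clade %||% rep("other", nrow(table)),
    brain_prop = table$neonatal_brain / table$adult_brain,
    body_prop = table$neonatal_body / table$maternal_body
  )
  over <- out$species[out$brain_prop > 1 | out$body_prop > 1]
  if (length(over)) {
    warn(paste0(
      "proportion(s) above 1 (possible data errors) for: ",
      paste(head(over, 5), collapse = ", ")
    ))
  }
  out
}

#' Pairwise Wilcoxon rank-sum tests with Bonferroni correction
#'
#' Two-sided Wilcoxon rank-sum test for every pair of groups, exact when both
#' group sizes are at most 25 and there are no ties, normal approximation
#' with continuity correction otherwise. The Bonferroni multiplier is the
#' number of pairs tested; adjusted p-values are capped at 1. Groups with
#' fewer than 2 members are excluded with a warning. The rank-based statistic
#' is invariant under strictly monotone transforms, so it is indifferent to
#' whether proportions are arcsine-transformed first.
#'
#' @param data a data frame (e.g. from [compute_proportions()]).
#' @param value column name of the variable compared.
#' @param group column name of the group labels.
#' @return a tibble with `group1`, `group2`, `n1`, `n2`, `statistic`,
#'   `p.value` (unadjusted), `p.adjusted`.
#' @export
pairwise_group_tests <- function(data, value, group = "clade") {
  v <- data[[value]]
  g <- as.character(data[[group]])
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warn(paste0(
      "group(s) with fewer than 2 members excluded: ",
      paste(small, collapse = ", ")
    ))
    keep <- !g %in% small
    v <- v[keep]
    g <- g[keep]
  }
  lev <- sort(unique(g))
  if (length(lev) < 2) abort("need at least 2 usable groups")
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  res <- purrr::map_dfr(pairs, function(pr) {
    a <- v[g == pr[1]]
    b <- v[g == pr[2]]
    exact <- length(a) <= 25 && length(b) <= 25 && !anyDuplicated(c(a, b))
    wt <- suppressWarnings(
      wilcox.test(a, b, exact = exact, correct = TRUE)
    )
    tibble(
      group1 = pr[1], group2 = pr[2],
      n1 = length(a), n2 = length(b),
      statistic = unname(wt$statistic), p.value = wt$p.value
    )
  })
  res$p.adjusted <- pmin(1, res$p.value * nrow(res))
  res
}

#' Group summary of proportions
#'
#' @param props tibble from [compute_proportions()].
#' @param value column to summarize.
#' @param group grouping column.
#' @return tibble with n, median, and interquartile range per group.
#' @export
proportion_summary <- function(props, value, group = "clade") {
  dplyr::summarise(
    dplyr::group_by(props, .data[[group]]),
    n = dplyr::n(),
    median = median(.data[[value]]),
    q25 = quantile(.data[[value]], 0.25),
    q75 = quantile(.data[[value]], 0.75),
    .groups = "drop"
  )
}
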