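#' Ancestral state reconstruction under Brownian motion
#'
#' Maximum-likelihood (GLS) ancestral states on a tree, optionally rescaled
#' by per-branch rate scalars (e.g. the posterior means from
#' [run_variable_rates()]). Estimates are the conditional expectations of the
#' node states given the tip data, with the root treated as a GLS-estimated
#' mean; they are computed by exact two-way Gaussian message passing in O(n)
#' and agree with the dense-matrix GLS solution. Tip "states" equal the
#' observed data with zero variance.
#'
#' @param tree a rooted `phylo`.
#' @param trait named numeric tip values.
#' @param scalars optional per-edge branch-length multipliers (one per row of
#'   `tree$edge`).
#' @return a tibble with one row per node (tips first, then internal nodes in
#'   `ape` numbering): `node`, `label` (tip label or `""`), `estimate`,
#'   `variance` (conditional variance, in squared trait units).
#' @examples
#' tr <- ape::rtree(6)
#' x <- stats::setNames(rnorm(6), tr$tip.label)
#' ancestral_states(tr, x)
#' @export
ancestral_states <- function(tree, trait, scalars = NULL) {
  len <- tree$edge.length
  if (!is.null(scalars)) {
    stopifnot(length(scalars) == nrow(tree$edge), all(scalars > 0))
    len <- len * scalars
  }
  bp <- bm_bp(tree, trait, len)
  sigma2 <- bp$Q / bp$n
  n <- bp$n
  tibble(
    node = seq_along(bp$mean),
    label = c(tree$tip.label, rep("", length(bp$mean) - n)),
    estimate = bp$mean,
    variance = bp$var * sigma2
  )
}
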