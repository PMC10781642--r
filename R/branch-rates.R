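#' Convert a phylogeny from Myr to generations
#'
#' Internal-node generation times are reconstructed by [ancestral_states()]
#' on the natural log of the tip generation times (optionally on a rescaled
#' tree); each branch is then converted as
#' `Myr * 1e6 / mean(parent, child generation time in years)`.
#'
#' @param tree a rooted `phylo` with branch lengths in Myr.
#' @param generation_times named numeric vector of tip generation times
#'   (years; age at first reproduction).
#' @param scalars optional per-edge scalars used for the reconstruction of
#'   ancestral generation times.
#' @return a list of class `generation_tree`: `tree` (the input tree),
#'   `edge_generations` (per-edge branch lengths in generations),
#'   `node_generation_times` (years, all nodes).
#' @export
to_generations <- function(tree, generation_times, scalars = NULL) {
  g <- check_tip_match(tree, generation_times)
  if (any(g <= 0)) abort("generation times must be > 0")
  anc <- ancestral_states(tree, log(g), scalars = scalars)
  gt <- exp(anc$estimate)
  n <- length(tree$tip.label)
  gt[seq_len(n)] <- g # tips keep observed values exactly
  gens <- tree$edge.length * 1e6 /
    ((gt[tree$edge[, 1]] + gt[tree$edge[, 2]]) / 2)
  structure(
    list(
      tree = tree,
      edge_generations = gens,
      node_generation_times = gt
    ),
    class = "generation_tree"
  )
}

gen_tree_phylo <- function(gtree) {
  tr <- gtree$tree
  tr$edge.length <- gtree$edge_generations
  tr
}

#' Tree-wide per-generation Brownian standard deviation
#'
#' Maximum-likelihood Brownian-motion variance of a trait per generation on
#' the generation-scaled (but rate-unscaled) tree, returned as a standard
#' deviation. This is the neutral-expectation scale parameter of the
#' branch-rate ratios.
#'
#' @param trait named numeric tip values (transformed scale).
#' @param gtree a `generation_tree` from [to_generations()].
#' @param method `"ML"` (variance = quadratic form / n) or `"REML"`
#'   (`/ (n - 1)`).
#' @return per-generation standard deviation (0 with a warning for a
#'   constant trait).
#' @export
estimate_sigma_g <- function(trait, gtree, method = c("ML", "REML")) {
  method <- match.arg(method)
  stopifnot(inherits(gtree, "generation_tree"))
  tr <- gen_tree_phylo(gtree)
  if (length(tr$tip.label) < 3) abort("need at least 3 tips")
  x <- check_tip_match(tr, trait)
  if (var(x) == 0) {
    warn("trait has zero variance; sigma_g = 0")
    return(0)
  }
  up <- bm_up_pass(tr, x)
  denom <- if (method == "ML") up$n else up$n - 1
  sqrt(up$Q / denom)
}

#' Branch-specific evolutionary-rate ratios
#'
#' For every branch, the observed change (descendant minus ancestral value,
#' from [ancestral_states()] on the rate-scaled generation tree) is divided
#' by the expected change under neutral homogeneous Brownian motion. The
#' signed ratio is the branch's evolutionary rate: |ratio| > 1 means more
#' change than expected (faster than neutral), values near 0 mean stasis,
#' and the sign gives the direction of change.
#'
#' With `calibrate = TRUE` (default) the expected change is the exact null
#' standard deviation of the *reconstructed* change,
#' `sigma_g * sqrt(effective generations)`, where the effective branch length
#' subtracts the variance absorbed by ancestral-state estimation; under a
#' neutral generator the ratios are then standard normal. With
#' `calibrate = FALSE` the raw branch length is used
#' (`sigma_g * sqrt(generations)`), which understates neutral spread because
#' reconstructed changes are shrunk towards zero.
#'
#' @param trait named numeric tip values (transformed scale).
#' @param gtree a `generation_tree`.
#' @param scalars optional per-edge rate scalars (posterior means from
#'   [run_variable_rates()]) used for the ancestral reconstruction only; the
#'   neutral expectation always uses the unscaled generation tree.
#' @param sigma_g per-generation standard deviation; estimated via
#'   [estimate_sigma_g()] when `NULL`.
#' @param calibrate use reconstruction-aware effective branch lengths (see
#'   Details).
#' @return a tibble with one row per branch: `edge`, `parent`, `child`,
#'   `species` (tip label for terminal branches), `generations`,
#'   `observed_change`, `expected_change`, `ratio`. Zero-length branches get
#'   `NA` ratios.
#' @export
branch_rate_ratios <- function(trait, gtree, scalars = NULL, sigma_g = NULL,
                               calibrate = TRUE) {
  stopifnot(inherits(gtree, "generation_tree"))
  tr <- gen_tree_phylo(gtree)
  x <- check_tip_match(tr, trait)
  sigma_g <- sigma_g %||% estimate_sigma_g(trait, gtree)
  if (sigma_g <= 0) abort("sigma_g must be > 0")
  len_scaled <- tr$edge.length
  if (!is.null(scalars)) {
    stopifnot(length(scalars) == nrow(tr$edge), all(scalars > 0))
    len_scaled <- len_scaled * scalars
  }
  bp <- bm_bp(tr, x, len_scaled)
  est <- bp$mean
  dx <- est[tr$edge[, 2]] - est[tr$edge[, 1]]
  if (calibrate) {
    ## effective lengths: branch length minus the variance absorbed by
    ## ancestral-state estimation, evaluated under the neutral (unscaled)
    ## generation tree
    eff <- if (is.null(scalars)) bp$eff_len else bm_bp(tr, x, tr$edge.length)$eff_len
  } else {
    eff <- tr$edge.length
  }
  expected <- sigma_g * sqrt(eff)
  ratio <- ifelse(expected > 0, dx / expected, NA_real_)
  ratio[gtree$edge_generations <= 0] <- NA_real_
  n <- length(tr$tip.label)
  tibble(
    edge = seq_len(nrow(tr$edge)),
    parent = tr$edge[, 1],
    child = tr$edge[, 2],
    species = ifelse(tr$edge[, 2] <= n, tr$tip.label[tr$edge[, 2]], NA_character_),
    generations = gtree$edge_generations,
    observed_change = dx,
    expected_change = expected,
    ratio = ratio
  )
}

#' Pairwise Pearson correlations between per-branch rates
#'
#' Branches are matched across traits by edge id. With
#' `remove_outliers = TRUE`, branches with a rate below -3 or above 3 in
#' either trait of a pair are excluded pairwise before correlating.
#'
#' @param rates named list of tibbles from [branch_rate_ratios()] (one per
#'   trait), all computed on the same tree.
#' @param remove_outliers exclude |ratio| > 3 branches pairwise.
#' @return a tibble with `trait_x`, `trait_y`, `r`, `p`, `n`,
#'   `outliers_removed`; pairs left with fewer than 3 branches get `NA` with
#'   a warning.
#' @export
rate_correlations <- function(rates, remove_outliers = FALSE) {
  stopifnot(is.list(rates), length(rates) >= 2, !is.null(names(rates)))
  traits <- names(rates)
  pairs <- utils::combn(traits, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    a <- rates[[pr[1]]]
    b <- rates[[pr[2]]]
    m <- dplyr::inner_join(
      a[c("edge", "ratio")], b[c("edge", "ratio")],
      by = "edge", suffix = c("_x", "_y")
    )
    m <- m[is.finite(m$ratio_x) & is.finite(m$ratio_y), ]
    if (remove_outliers) {
      keep <- abs(m$ratio_x) <= 3 & abs(m$ratio_y) <= 3
      m <- m[keep, ]
    }
    if (nrow(m) < 3) {
      warn(paste0("fewer than 3 shared branches for ", pr[1], " vs ", pr[2]))
      return(tibble(
        trait_x = pr[1], trait_y = pr[2], r = NA_real_, p = NA_real_,
        n = nrow(m), outliers_removed = remove_outliers
      ))
    }
    ct <- cor.test(m$ratio_x, m$ratio_y)
    tibble(
      trait_x = pr[1], trait_y = pr[2],
      r = unname(ct$estimate), p = ct$p.value, n = nrow(m),
      outliers_removed = remove_outliers
    )
  })
}

#' Correlation of unsigned rates with branch length
#'
#' Pearson correlation between |ratio| and branch length, reported separately
#' in Myr and in generations.
#'
#' @param rates a tibble from [branch_rate_ratios()].
#' @param gtree the `generation_tree` the rates were computed on.
#' @return a tibble with rows `Myr` and `generations`: `scale`, `r`, `p`,
#'   `n`. Constant |ratio| yields `NA` with a warning.
#' @export
rate_vs_branchlength <- function(rates, gtree) {
  stopifnot(inherits(gtree, "generation_tree"))
  a <- abs(rates$ratio)
  purrr::map_dfr(
    list(
      list(scale = "Myr", len = gtree$tree$edge.length),
      list(scale = "generations", len = gtree$edge_generations)
    ),
    function(s) {
      ok <- is.finite(a) & is.finite(s$len)
      if (sum(ok) < 3 || sd(a[ok]) == 0 || sd(s$len[ok]) == 0) {
        warn(paste0("rate vs branch length (", s$scale, ") undefined"))
        return(tibble(scale = s$scale, r = NA_real_, p = NA_real_, n = sum(ok)))
      }
      ct <- cor.test(a[ok], s$len[ok])
      tibble(scale = s$scale, r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
    }
  )
}

#' Counterfactual terminal-branch rate
#'
#' Replaces one species' trait value with a hypothetical value, re-runs the
#' rate pipeline, and returns the species' terminal-branch ratio: the
#' evolutionary rate that would have been required for the species to reach
#' the hypothetical value from its ancestor.
#'
#' @param table a species table (see [read_species_table()]).
#' @param tree matching phylogeny (Myr).
#' @param species focal species name.
#' @param trait trait column name in `table`.
#' @param hypothetical_value replacement value on the raw scale.
#' @param transform transform tag applied to the trait column
#'   (see [transform_trait()]).
#' @param mode `"fast"` keeps unit scalars (fixed homogeneous reconstruction);
#'   `"full"` re-runs the variable-rates MCMC on the modified data.
#' @param config [mcmc_config()] used when `mode = "full"`.
#' @param calibrate passed to [branch_rate_ratios()].
#' @return one row of the [branch_rate_ratios()] tibble (the focal species'
#'   terminal branch), with the full rate table in attribute `rates`.
#' @export
counterfactual_rate <- function(table, tree, species, trait,
                                hypothetical_value,
                                transform = "log",
                                mode = c("fast", "full"),
                                config = mcmc_config(),
                                calibrate = TRUE) {
  mode <- match.arg(mode)
  if (!species %in% table$species) {
    abort(paste0("species not in table: ", species))
  }
  if (transform == "log" && hypothetical_value <= 0) {
    abort("hypothetical value must be > 0 under a log transform")
  }
  tab <- table
  tab[[trait]][tab$species == species] <- hypothetical_value
  mp <- match_and_prune(tree, tab)
  x <- setNames(
    transform_trait(mp$table[[trait]], transform),
    mp$table$species
  )
  gtree <- to_generations(
    mp$tree, setNames(mp$table$generation_time, mp$table$species)
  )
  scal <- NULL
  if (mode == "full") {
    fit <- run_variable_rates(gen_tree_phylo(gtree), x, config)
    scal <- fit$scalars$scalar
  }
  rr <- branch_rate_ratios(x, gtree, scalars = scal, calibrate = calibrate)
  out <- rr[!is.na(rr$species) & rr$species == species, ]
  attr(out, "rates") <- rr
  out
}
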