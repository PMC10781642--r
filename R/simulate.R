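#' Simulate a pure-birth (Yule) time tree
#'
#' Wraps [ape::rphylo()] with extinction fixed at zero. Branch lengths are in
#' Myr. Fully deterministic under `seed`.
#'
#' @param n_tips number of tips (>= 3).
#' @param birth_rate per-Myr speciation rate.
#' @param seed integer seed.
#' @return an ultrametric binary `phylo` with tip labels `t1..tn`.
#' @export
simulate_tree <- function(n_tips, birth_rate = 0.1, seed = 1) {
  if (n_tips < 3) abort("n_tips must be >= 3")
  if (birth_rate <= 0) abort("birth_rate must be > 0")
  set.seed(seed)
  ape::rphylo(n_tips, birth = birth_rate, death = 0)
}

#' Default simulation configuration
#'
#' The defaults emulate the scale of the mammalian study system: 140 tips in
#' four labelled clades, root generation time 8 years evolving as Brownian
#' motion on the natural-log scale (reflected at a 0.1-year floor), and
#' log-linear neonatal-to-adult allometries with Brownian residual noise.
#'
#' @param n_tips number of tips.
#' @param birth_rate Yule speciation rate per Myr.
#' @param seed integer seed; fully determines all outputs.
#' @param sigma_per_gen per-generation Brownian standard deviation of the
#'   focal trait(s).
#' @param shift_spec list of `list(edge = i, scalar = s)` entries planting a
#'   rate shift (the scalar multiplies the Brownian standard deviation) on
#'   edge `i` of the tree (row of `tree$edge`).
#' @param allometry list with per-trait-pair `c(intercept, slope, resid_sd)`
#'   entries named `brain` and `body` (natural-log scale).
#' @param gen_time_params `c(root_years, bm_sd_ln_per_sqrt_myr)` for the
#'   generation-time Brownian motion on the log scale.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_tips = 140, birth_rate = 0.1, seed = 1,
                       sigma_per_gen = 5e-4,
                       shift_spec = list(),
                       allometry = list(
                         brain = c(intercept = 1.2, slope = 0.95, resid_sd = 0.25),
                         body = c(intercept = 3.0, slope = 1.0, resid_sd = 0.3)
                       ),
                       gen_time_params = c(root_years = 8, bm_sd = 0.05)) {
  stopifnot(n_tips >= 3, birth_rate > 0, sigma_per_gen >= 0)
  for (s in shift_spec) {
    if (is.null(s$edge) || is.null(s$scalar) || s$scalar <= 0) {
      abort("each shift_spec entry needs an edge id and a scalar > 0")
    }
  }
  structure(
    list(
      n_tips = n_tips, birth_rate = birth_rate, seed = seed,
      sigma_per_gen = sigma_per_gen, shift_spec = shift_spec,
      allometry = allometry, gen_time_params = gen_time_params
    ),
    class = "sim_config"
  )
}

## simulate ln generation times down the tree (BM per sqrt(Myr)), reflected
## at a 0.1-year floor; returns values for all nodes (root first recursion)
sim_generation_times <- function(tree, root_years, bm_sd) {
  n <- length(tree$tip.label)
  N <- n + tree$Nnode
  ord <- po_order(tree)
  lg <- numeric(N)
  lg[n + 1L] <- log(root_years)
  floor_ln <- log(0.1)
  for (i in rev(ord)) {
    p <- tree$edge[i, 1]
    ch <- tree$edge[i, 2]
    v <- lg[p] + rnorm(1, 0, bm_sd * sqrt(tree$edge.length[i]))
    if (v < floor_ln) v <- 2 * floor_ln - v # reflect at the floor
    lg[ch] <- v
  }
  exp(lg)
}

## branch lengths in generations from per-node generation times (years):
## Myr * 1e6 / mean(parent, child generation time)
edge_generations <- function(tree, gen_times) {
  g <- (gen_times[tree$edge[, 1]] + gen_times[tree$edge[, 2]]) / 2
  tree$edge.length * 1e6 / g
}

#' Simulate Brownian traits with planted branch-rate shifts
#'
#' The trait evolves root-to-tips with per-branch variance
#' `sigma_per_gen^2 * generations * scalar^2`, where branch generations come
#' from a Brownian-motion generation-time process on the log scale and
#' `scalar` is 1 except on branches named in `config$shift_spec`. Results are
#' deterministic under `config$seed`.
#'
#' @param tree a binary `phylo` (Myr branch lengths).
#' @param config a [sim_config()].
#' @param root_value trait value at the root.
#' @return a list with `trait` (named tip values), `truth` (a list holding
#'   per-node true values, per-node generation times, per-edge generations and
#'   sd scalars), deterministic under `config$seed`.
#' @export
simulate_bm_traits <- function(tree, config = sim_config(), root_value = 0) {
  n <- length(tree$tip.label)
  N <- n + tree$Nnode
  nE <- nrow(tree$edge)
  scal <- rep(1, nE)
  for (s in config$shift_spec) {
    if (s$edge < 1 || s$edge > nE) {
      abort(paste0("shift_spec edge ", s$edge, " not in tree (", nE, " edges)"))
    }
    scal[s$edge] <- s$scalar
  }
  set.seed(config$seed)
  g <- sim_generation_times(
    tree, config$gen_time_params[[1]], config$gen_time_params[[2]]
  )
  gens <- edge_generations(tree, g)
  xv <- numeric(N)
  xv[n + 1L] <- root_value
  ord <- po_order(tree)
  for (i in rev(ord)) {
    p <- tree$edge[i, 1]
    ch <- tree$edge[i, 2]
    xv[ch] <- xv[p] +
      rnorm(1, 0, config$sigma_per_gen * sqrt(gens[i]) * scal[i])
  }
  trait <- setNames(xv[seq_len(n)], tree$tip.label)
  list(
    trait = trait,
    truth = list(
      node_values = xv,
      generation_times = g,
      edge_generations = gens,
      edge_sd_scalars = scal,
      sigma_per_gen = config$sigma_per_gen
    )
  )
}

## assign tips to k clade labels by repeatedly splitting the largest subtree
clade_labels <- function(tree, labels = c("Primates", "Artiodactyla",
                                          "Carnivora", "Rodentia", "other")) {
  n <- length(tree$tip.label)
  tips_below <- function(node) {
    if (node <= n) return(node)
    unlist(lapply(tree$edge[tree$edge[, 1] == node, 2], tips_below))
  }
  groups <- list(n + 1L)
  while (length(groups) < length(labels)) {
    sizes <- vapply(groups, function(nd) length(tips_below(nd)), integer(1))
    big <- which.max(sizes)
    node <- groups[[big]]
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    kids <- kids[kids > n]
    if (!length(kids)) break
    ## replace the biggest group by the split of its largest internal child
    repl <- c(
      as.list(tree$edge[tree$edge[, 1] == node, 2]),
      groups[-big]
    )
    groups <- repl
  }
  sizes <- vapply(groups, function(nd) length(tips_below(nd)), integer(1))
  groups <- groups[order(-sizes)]
  lab <- rep(labels[length(labels)], n)
  for (i in seq_len(min(length(labels) - 1, length(groups)))) {
    lab[tips_below(groups[[i]])] <- labels[i]
  }
  setNames(lab, tree$tip.label)
}

#' Simulate a full species trait table
#'
#' Log neonatal brain and body masses evolve as Brownian motion on the
#' generation-scaled tree; adult (maternal) values follow the configured
#' log-linear allometries with Gaussian residuals; gestation length evolves
#' as Brownian motion on the log scale. The table always passes
#' [validate_species_table()].
#'
#' @param tree a `phylo`; defaults to a fresh Yule tree from the config.
#' @param config a [sim_config()].
#' @return a list with `table` (species tibble), `tree`, and `truth`.
#' @export
simulate_species_table <- function(tree = NULL, config = sim_config()) {
  if (is.null(tree)) {
    tree <- simulate_tree(config$n_tips, config$birth_rate, config$seed)
  }
  n <- length(tree$tip.label)
  set.seed(config$seed + 1L)
  g <- sim_generation_times(
    tree, config$gen_time_params[[1]], config$gen_time_params[[2]]
  )
  gens <- edge_generations(tree, g)
  sim_bm_on <- function(root_value, sd_per_gen) {
    xv <- numeric(n + tree$Nnode)
    xv[n + 1L] <- root_value
    for (i in rev(po_order(tree))) {
      xv[tree$edge[i, 2]] <- xv[tree$edge[i, 1]] +
        rnorm(1, 0, sd_per_gen * sqrt(gens[i]))
    }
    xv
  }
  ln_neo_brain <- sim_bm_on(log(20), config$sigma_per_gen)
  ln_neo_body <- sim_bm_on(log(300), config$sigma_per_gen)
  ln_gest <- sim_bm_on(log(150), config$sigma_per_gen / 2)
  ab <- config$allometry$brain
  bb <- config$allometry$body
  tipi <- seq_len(n)
  ln_adult_brain <- ab[["intercept"]] + ab[["slope"]] * ln_neo_brain[tipi] +
    rnorm(n, 0, ab[["resid_sd"]])
  ln_maternal <- bb[["intercept"]] + bb[["slope"]] * ln_neo_body[tipi] +
    rnorm(n, 0, bb[["resid_sd"]])
  tab <- tibble(
    species = tree$tip.label,
    neonatal_brain = exp(ln_neo_brain[tipi]),
    adult_brain = exp(ln_adult_brain),
    neonatal_body = exp(ln_neo_body[tipi]),
    maternal_body = exp(ln_maternal),
    gestation = exp(ln_gest[tipi]),
    generation_time = g[tipi],
    clade = unname(clade_labels(tree))
  )
  ## adult brain must exceed neonatal brain for a plausible mammal table?
  ## no: data may violate neonatal < adult, and so may the generator.
  truth <- list(
    generation_times = g, edge_generations = gens,
    ln_neonatal_brain_nodes = ln_neo_brain,
    ln_neonatal_body_nodes = ln_neo_body,
    ln_gestation_nodes = ln_gest,
    allometry = config$allometry
  )
  list(table = validate_species_table(tab), tree = tree, truth = truth)
}

#' Neurodevelopmental event fixture
#'
#' Returns the 13 landmark brain-development events whose pre/postnatal
#' occurrence changes across hominins (labels and event scores as printed in
#' the source compilation), optionally padded with synthetic filler events to
#' a full table of brain-development events. Filler scores are drawn outside
#' the \[0.66, 0.78\] band: empirically no other brain-development event score
#' falls inside the hominin shift window, and the filler preserves that
#' feature so window-based counts behave like the real table.
#'
#' @param n_filler number of synthetic filler events to append (e.g. 202 for
#'   a 215-row table).
#' @param seed seed for the filler scores.
#' @return a tibble with columns `label`, `score`, `category`,
#'   `cortical_neurogenesis`.
#' @export
fixture_event_table <- function(n_filler = 0, seed = 1) {
  core <- tibble(
    label = c(
      "fornix myelination onset",
      "anterior commissure myelination onset",
      "lateral geniculate nucleus myelination onset",
      "cingulum myelination onset",
      "mammillothalamic tract myelination onset",
      "internal capsule myelination onset",
      "hippocampus myelination onset",
      "fasciculus retroflexus myelination onset",
      "stria terminalis myelination onset",
      "striatum myelination onset",
      "corpus callosum body myelination onset",
      "splenium myelination onset",
      "plasticity/ocular dominance critical period start"
    ),
    score = c(
      0.675, 0.677, 0.68, 0.687, 0.689, 0.692, 0.699, 0.7, 0.703,
      0.715, 0.722, 0.732, 0.77
    ),
    category = c(rep("limbic", 12), "cortex"),
    cortical_neurogenesis = 0
  )
  if (n_filler > 0) {
    set.seed(seed)
    sc <- numeric(0)
    while (length(sc) < n_filler) {
      cand <- runif(n_filler * 2)
      cand <- cand[cand < 0.66 | cand > 0.78]
      sc <- c(sc, cand)
    }
    sc <- sc[seq_len(n_filler)]
    filler <- tibble(
      label = sprintf("synthetic event %03d", seq_len(n_filler)),
      score = sc,
      category = sample(
        c("brainstem", "cerebellum", "thalamus", "cortex"),
        n_filler, replace = TRUE
      ),
      cortical_neurogenesis = 0
    )
    core <- dplyr::bind_rows(core, filler)
  }
  core
}
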