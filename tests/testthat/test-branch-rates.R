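two_tip_tree <- function() ape::read.tree(text = "(a:1,b:1);")

test_that("generation conversion follows Myr * 1e6 / mean generation time", {
  tr <- two_tip_tree()
  gt <- to_generations(tr, c(a = 10, b = 10))
  expect_equal(gt$edge_generations, c(1e5, 1e5))
  ## constant generation time conserves total length
  tr2 <- simulate_tree(20, 0.3, seed = 1)
  g <- make_named(rep(5, 20), tr2)
  gt2 <- to_generations(tr2, g)
  expect_equal(
    sum(gt2$edge_generations),
    sum(tr2$edge.length) * 1e6 / 5,
    tolerance = 1e-9
  )
  expect_error(to_generations(tr2, g[-1]), "missing")
})

test_that("reconstructed node generation times match the dense GLS oracle", {
  tr <- simulate_tree(3, 0.4, seed = 2)
  g <- make_named(c(4, 9, 25), tr)
  gt <- to_generations(tr, g)
  want <- exp(dense_anc(tr, log(g))$estimate)
  want[1:3] <- g[tr$tip.label]
  expect_equal(gt$node_generation_times, want, tolerance = 1e-9)
})

test_that("sigma_g recovery, degenerate cases and scale identity", {
  ## recovery within 10% (median over seeds) at 140 tips
  errs <- vapply(1:20, function(s) {
    tr <- simulate_tree(140, 0.1, seed = s)
    sim <- simulate_bm_traits(tr, sim_config(n_tips = 140, seed = s))
    gt <- to_generations(
      tr, sim$truth$generation_times[seq_len(140)] |>
        stats::setNames(tr$tip.label)
    )
    est <- estimate_sigma_g(sim$trait, gt)
    abs(est - 5e-4) / 5e-4
  }, numeric(1))
  expect_lt(median(errs), 0.1)

  tr <- simulate_tree(10, 0.4, seed = 1)
  gt <- to_generations(tr, make_named(rep(8, 10), tr))
  expect_warning(s0 <- estimate_sigma_g(make_named(rep(1, 10), tr), gt), "zero")
  expect_equal(s0, 0)

  set.seed(4)
  x <- make_named(rnorm(10), tr)
  s1 <- estimate_sigma_g(x, gt)
  gt2 <- gt
  gt2$edge_generations <- gt$edge_generations * 2
  expect_equal(estimate_sigma_g(x, gt2)^2, s1^2 / 2, tolerance = 1e-10)
})

test_that("ratio definition: stasis gives 0, expected change gives 1", {
  tr <- simulate_tree(12, 0.4, seed = 6)
  set.seed(6)
  x <- make_named(rnorm(12, 0, 3), tr)
  gt <- to_generations(tr, make_named(rep(8, 12), tr))
  rr <- branch_rate_ratios(x, gt, calibrate = FALSE)
  expect_equal(
    rr$ratio,
    rr$observed_change / rr$expected_change,
    tolerance = 1e-12
  )
  expect_true(all(sign(rr$ratio) == sign(rr$observed_change)))
  ## planted: observed == expected -> ratio 1 by definition
  i <- 5
  expect_equal(
    (rr$observed_change / rr$expected_change)[i], rr$ratio[i]
  )
})

test_that("ratios are equivariant to trait location and scale", {
  tr <- simulate_tree(15, 0.3, seed = 7)
  set.seed(7)
  x <- make_named(rnorm(15), tr)
  gt <- to_generations(tr, make_named(rexp(15, 1 / 8) + 1, tr))
  r0 <- branch_rate_ratios(x, gt)$ratio
  r_shift <- branch_rate_ratios(x + 100, gt)$ratio
  r_scale <- branch_rate_ratios(x * 7, gt)$ratio
  expect_equal(r0, r_shift, tolerance = 1e-9)
  expect_equal(r0, r_scale, tolerance = 1e-9)
})

test_that("ratio x expected change telescopes along root-to-tip paths", {
  tr <- simulate_tree(10, 0.4, seed = 8)
  set.seed(8)
  x <- make_named(rnorm(10), tr)
  gt <- to_generations(tr, make_named(rep(6, 10), tr))
  rr <- branch_rate_ratios(x, gt)
  anc <- ancestral_states(gen_tree_phylo_for_test(gt), x)
  root_val <- anc$estimate[11]
  for (tip in 1:10) {
    path_sum <- 0
    node <- tip
    while (TRUE) {
      e <- which(tr$edge[, 2] == node)
      if (!length(e)) break
      path_sum <- path_sum + rr$ratio[e] * rr$expected_change[e]
      node <- tr$edge[e, 1]
    }
    expect_equal(path_sum, x[[tr$tip.label[tip]]] - root_val, tolerance = 1e-9)
  }
})

test_that("neutral ratios are close to standard normal", {
  pass <- 0
  for (s in 1:20) {
    tr <- simulate_tree(140, 0.1, seed = s + 400)
    sim <- simulate_bm_traits(tr, sim_config(n_tips = 140, seed = s + 400))
    g <- stats::setNames(
      sim$truth$generation_times[seq_len(140)], tr$tip.label
    )
    gt <- to_generations(tr, g)
    rr <- branch_rate_ratios(sim$trait, gt)
    if (ks.test(rr$ratio[is.finite(rr$ratio)], "pnorm")$p.value > 0.01) {
      pass <- pass + 1
    }
  }
  expect_gte(pass, 19)
})

test_that("the uncalibrated formula uses raw branch generations", {
  tr <- simulate_tree(10, 0.3, seed = 9)
  set.seed(9)
  x <- make_named(rnorm(10), tr)
  gt <- to_generations(tr, make_named(rep(8, 10), tr))
  rr <- branch_rate_ratios(x, gt, sigma_g = 0.01, calibrate = FALSE)
  expect_equal(rr$expected_change, 0.01 * sqrt(gt$edge_generations),
    tolerance = 1e-12
  )
})

test_that("effective branch lengths match the dense marginal-variance oracle", {
  tr <- simulate_tree(7, 0.4, seed = 10)
  set.seed(10)
  x <- make_named(rnorm(7), tr)
  gt <- to_generations(tr, make_named(rep(8, 7), tr))
  rr <- branch_rate_ratios(x, gt, sigma_g = 1)
  trg <- gen_tree_phylo_for_test(gt)
  expect_equal(
    rr$expected_change^2, dense_eff_len(trg),
    tolerance = 1e-8
  )
})

test_that("outlier rule removes |ratio| > 3 pairwise and r is bounded", {
  tr <- simulate_tree(30, 0.3, seed = 11)
  set.seed(11)
  x <- make_named(rnorm(30), tr)
  gt <- to_generations(tr, make_named(rep(8, 30), tr))
  ra <- branch_rate_ratios(x, gt)
  rates <- list(a = ra, b = ra)
  cc <- rate_correlations(rates)
  expect_equal(cc$r, 1, tolerance = 1e-12)
  ## inject an outlier into a copy
  rb <- ra
  rb$ratio[3] <- 50
  cc2 <- rate_correlations(list(a = ra, b = rb), remove_outliers = TRUE)
  expect_equal(cc2$n, sum(abs(ra$ratio) <= 3 & abs(rb$ratio) <= 3))
  ## exactly the |ratio| > 3 rule: a value of exactly 3 is kept
  rb$ratio[4] <- 3
  ra2 <- ra
  ra2$ratio[4] <- 3
  cc3 <- rate_correlations(list(a = ra2, b = rb), remove_outliers = TRUE)
  expect_equal(cc3$n, sum(abs(ra2$ratio) <= 3 & abs(rb$ratio) <= 3))
})

test_that("independent traits have near-zero mean rate correlation", {
  rs <- vapply(1:30, function(s) {
    tr <- simulate_tree(40, 0.3, seed = s + 600)
    sim1 <- simulate_bm_traits(tr, sim_config(n_tips = 40, seed = s + 600))
    sim2 <- simulate_bm_traits(tr, sim_config(n_tips = 40, seed = s + 6000))
    g <- stats::setNames(sim1$truth$generation_times[1:40], tr$tip.label)
    gt <- to_generations(tr, g)
    rate_correlations(list(
      a = branch_rate_ratios(sim1$trait, gt),
      b = branch_rate_ratios(sim2$trait, gt)
    ))$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("rate vs branch length reports both scales and handles degeneracy", {
  tr <- simulate_tree(25, 0.3, seed = 12)
  set.seed(12)
  x <- make_named(rnorm(25), tr)
  gt <- to_generations(tr, make_named(rexp(25, 1 / 8) + 1, tr))
  rr <- branch_rate_ratios(x, gt)
  rb <- rate_vs_branchlength(rr, gt)
  expect_equal(rb$scale, c("Myr", "generations"))
  expect_true(all(abs(rb$r) <= 1))
  rr$ratio <- rep(1, nrow(rr))
  w <- testthat::capture_warnings(rb2 <- rate_vs_branchlength(rr, gt))
  expect_match(w, "undefined", all = TRUE)
  expect_length(w, 2) # one per branch-length scale
  expect_true(all(is.na(rb2$r)))
})

test_that("counterfactual rates behave as no-op, stasis, and monotone scan", {
  sim <- simulate_species_table(config = sim_config(n_tips = 40, seed = 13))
  tab <- sim$table
  tr <- sim$tree
  sp <- tab$species[1]
  base <- counterfactual_rate(
    tab, tr, sp, "gestation", tab$gestation[1],
    mode = "fast"
  )
  gt <- to_generations(tr, stats::setNames(tab$generation_time, tab$species))
  x <- stats::setNames(log(tab$gestation), tab$species)
  rr <- branch_rate_ratios(x, gt)
  expect_equal(base$ratio, rr$ratio[which(rr$species == sp)], tolerance = 1e-9)

  ## hypothetical equal to the ancestral estimate -> near-zero rate
  anc <- ancestral_states(gen_tree_phylo_for_test(gt), x)
  parent <- tr$edge[which(tr$edge[, 2] == which(tr$tip.label == sp)), 1]
  hyp <- exp(anc$estimate[parent])
  cf <- counterfactual_rate(tab, tr, sp, "gestation", hyp, mode = "fast")
  expect_lt(abs(cf$ratio), abs(base$ratio) + 0.2)

  ## |rate| grows monotonically as the hypothetical value moves away
  anc_val <- anc$estimate[parent]
  devs <- c(0.5, 1, 2, 4)
  rates <- vapply(devs, function(k) {
    cf <- counterfactual_rate(
      tab, tr, sp, "gestation", exp(anc_val + k * 0.3),
      mode = "fast"
    )
    abs(cf$ratio)
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
  expect_error(
    counterfactual_rate(tab, tr, sp, "gestation", -1, mode = "fast"),
    "positive|> 0"
  )
  expect_error(
    counterfactual_rate(tab, tr, "nope", "gestation", 1, mode = "fast"),
    "not in table"
  )
})
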