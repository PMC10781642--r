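star_tree <- function(n, len = 1) {
  txt <- paste0("(", paste0("s", 1:n, ":", len, collapse = ","), ");")
  ape::read.tree(text = txt)
}

sim_xy <- function(tree, slope = 0.8, intercept = 1, resid_sd = 0.5, seed = 1) {
  set.seed(seed)
  n <- ape::Ntip(tree)
  x <- ape::rTraitCont(tree, sigma = 1)[tree$tip.label]
  e <- ape::rTraitCont(tree, sigma = resid_sd)[tree$tip.label]
  tibble::tibble(
    species = tree$tip.label,
    x = as.numeric(x),
    y = intercept + slope * as.numeric(x) + as.numeric(e)
  )
}

test_that("PGLS reduces to OLS on a star tree", {
  tr <- star_tree(12)
  d <- sim_xy(tr, seed = 2)
  f <- pgls_fit(d, "x", "y", tr)
  ols <- stats::lm(y ~ x, data = d)
  expect_equal(unname(f$coefficients), unname(stats::coef(ols)),
    tolerance = 1e-10
  )
  expect_equal(unname(f$se), unname(sqrt(diag(stats::vcov(ols)))),
    tolerance = 1e-10
  )
})

test_that("noiseless data recover the slope exactly", {
  tr <- simulate_tree(20, 0.3, seed = 3)
  d <- sim_xy(tr, slope = 1.7, resid_sd = 0, seed = 3)
  f <- pgls_fit(d, "x", "y", tr)
  expect_equal(f$coefficients[[2]], 1.7, tolerance = 1e-10)
})

test_that("five-tip PGLS matches the dense GLS oracle to 1e-10", {
  tr <- simulate_tree(5, 0.5, seed = 4)
  d <- sim_xy(tr, seed = 4)
  f <- pgls_fit(d, "x", "y", tr)
  C <- ape::vcv(tr)
  Ci <- solve(C)
  X <- cbind(1, d$x[match(rownames(C), d$species)])
  yv <- d$y[match(rownames(C), d$species)]
  beta <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% yv)
  expect_equal(unname(f$coefficients), as.numeric(beta), tolerance = 1e-10)
  res <- yv - X %*% beta
  s2 <- as.numeric(t(res) %*% Ci %*% res) / (5 - 2)
  expect_equal(f$sigma2, s2, tolerance = 1e-10)
  expect_equal(
    unname(f$se),
    sqrt(diag(solve(t(X) %*% Ci %*% X)) * s2),
    tolerance = 1e-10
  )
})

test_that("PGLS agrees with nlme::gls under Brownian correlation", {
  skip_if_not_installed("nlme")
  tr <- simulate_tree(25, 0.3, seed = 5)
  d <- sim_xy(tr, seed = 5)
  f <- pgls_fit(d, "x", "y", tr)
  gfit <- nlme::gls(
    y ~ x,
    data = as.data.frame(d),
    correlation = ape::corBrownian(1, tr, form = ~species)
  )
  expect_equal(unname(f$coefficients), unname(stats::coef(gfit)),
    tolerance = 1e-6
  )
})

test_that("GLS residuals have zero GLS mean", {
  tr <- simulate_tree(15, 0.3, seed = 6)
  d <- sim_xy(tr, seed = 6)
  f <- pgls_fit(d, "x", "y", tr)
  C <- ape::vcv(tr)[names(f$residuals), names(f$residuals)]
  expect_lt(abs(sum(solve(C) %*% f$residuals)), 1e-8)
})

test_that("pancova F is nonnegative and detects planted intercept offsets", {
  tr <- simulate_tree(40, 0.3, seed = 7)
  d <- sim_xy(tr, seed = 7)
  set.seed(7)
  d$g <- sample(rep(c("A", "B"), each = 20))
  r0 <- pancova(d, "x", "y", tr, "g")
  expect_gte(r0$F, 0)
  expect_true(r0$p.value >= 0 && r0$p.value <= 1)
  ## displace group B by five residual sds
  d2 <- d
  d2$y[d2$g == "B"] <- d2$y[d2$g == "B"] + 5 * 0.5
  r1 <- pancova(d2, "x", "y", tr, "g")
  expect_lt(r1$p.value, 0.05)
  expect_gt(r1$F, r0$F)
  lines <- attr(r1, "group_lines")
  expect_equal(lines$group, c("A", "B"))
  expect_gt(lines$intercept[2], lines$intercept[1])
})

test_that("pancova type-I error is near nominal under the Brownian null", {
  rej <- 0
  nsim <- 150
  for (s in seq_len(nsim)) {
    tr <- simulate_tree(30, 0.3, seed = s + 100)
    d <- sim_xy(tr, seed = s + 100)
    set.seed(s)
    d$g <- sample(rep(c("A", "B"), each = 15))
    if (pancova(d, "x", "y", tr, "g")$p.value < 0.05) rej <- rej + 1
  }
  expect_gt(rej / nsim, 0.01)
  expect_lt(rej / nsim, 0.11)
})

test_that("slope-and-intercept test needs the interaction term", {
  tr <- simulate_tree(40, 0.3, seed = 8)
  d <- sim_xy(tr, seed = 8)
  set.seed(8)
  d$g <- sample(rep(c("A", "B"), each = 20))
  d$y[d$g == "B"] <- d$y[d$g == "B"] + 2 * d$x[d$g == "B"]
  r <- pancova(d, "x", "y", tr, "g", test = "slope_and_intercept")
  expect_lt(r$p.value, 0.01)
  expect_error(pancova(d[1:5, ], "x", "y", tr, "g"), "3")
})

test_that("a species exactly on the rest-of-group line gives F = 0", {
  tr <- star_tree(10)
  d <- sim_xy(tr, seed = 9)
  rest <- stats::lm(y ~ x, data = d[-1, ])
  d$y[1] <- stats::predict(rest, d[1, ])
  r <- single_species_test(d, "x", "y", tr, d$species[1])
  expect_equal(r$F, 0, tolerance = 1e-9)
  expect_equal(r$p.value, 1, tolerance = 1e-6)
})

test_that("a strongly displaced species is detected and order does not matter", {
  tr <- simulate_tree(20, 0.3, seed = 10)
  d <- sim_xy(tr, seed = 10, resid_sd = 0.5)
  d$y[3] <- d$y[3] + 10 * 0.5
  r1 <- single_species_test(d, "x", "y", tr, d$species[3])
  expect_lt(r1$p.value, 0.01)
  d_shuffled <- d[sample(nrow(d)), ]
  r2 <- single_species_test(d_shuffled, "x", "y", tr, d$species[3])
  expect_equal(r1$F, r2$F, tolerance = 1e-9)
  expect_error(single_species_test(d, "x", "y", tr, "missing species"), "not found")
})

test_that("slope CIs cover the truth at the nominal rate", {
  cov <- 0
  nsim <- 60
  for (s in seq_len(nsim)) {
    tr <- simulate_tree(30, 0.3, seed = s + 300)
    d <- sim_xy(tr, slope = 0.8, seed = s + 300)
    f <- pgls_fit(d, "x", "y", tr)
    ci <- f$coefficients[2] + c(-1, 1) * qt(0.975, f$df.residual) * f$se[2]
    if (ci[1] <= 0.8 && 0.8 <= ci[2]) cov <- cov + 1
  }
  expect_gte(cov / nsim, 0.85)
})

test_that("driver decomposition classifies planted departures", {
  ## star tree: the focal ancestor is the root, so an inflated response moves
  ## the reconstruction only by ~1/n and the planted effect is recovered
  tr <- star_tree(25)
  d <- sim_xy(tr, slope = 1, intercept = 0, resid_sd = 0.2, seed = 11)
  sp <- d$species[1]
  base <- driver_decomposition(d, "x", "y", tr, sp)
  d2 <- d
  d2$y[1] <- d2$y[1] + 1.0
  dd <- driver_decomposition(d2, "x", "y", tr, sp)
  expect_equal(dd$departure - base$departure, 1.0, tolerance = 0.1)
  expect_equal(dd$delta_x, base$delta_x, tolerance = 1e-9)
  ## proportional case: response change exactly slope * predictor change
  expect_equal(base$expected_delta_y,
    base$delta_y - base$departure,
    tolerance = 1e-12
  )
})

test_that("prediction intervals are wider than confidence intervals", {
  tr <- simulate_tree(20, 0.3, seed = 12)
  d <- sim_xy(tr, seed = 12)
  f <- pgls_fit(d, "x", "y", tr)
  ci <- predict(f, interval = "confidence")
  pi_ <- predict(f, interval = "prediction")
  expect_true(all(pi_$upr - pi_$lwr > ci$upr - ci$lwr))
  td <- tidy(f)
  expect_equal(td$term, c("(Intercept)", "x"))
  expect_s3_class(autoplot(f), "ggplot")
})
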