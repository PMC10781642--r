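hominin_fixture <- function() {
  read_hominin_table(
    system.file("extdata", "hominins_synthetic.csv", package = "altrix")
  )
}

test_that("species parameters evaluate the printed formulas with natural logs", {
  p <- species_params(275, 1330)
  expect_equal(p$intercept, 1.241 + 0.368 * log(275), tolerance = 1e-12)
  expect_equal(round(p$intercept, 4), 3.308)
  expect_equal(species_params(275, 1)$slope, 1.474)
  expect_equal(species_params(227, 390)$intercept, 3.2373, tolerance = 1e-4)
  expect_error(species_params(-1, 100), "> 0")
})

test_that("event days order with score and classify around birth", {
  p <- species_params(275, 1330)
  ev <- fixture_event_table()
  td <- event_day(p, ev)
  expect_true(all(diff(td$post_conception_day) > 0)) # slope > 0
  ## plasticity onset (0.77) is postnatal in humans; fornix (0.675) prenatal
  expect_equal(td$classification[td$score == 0.77], "postnatal")
  expect_equal(td$classification[td$score == 0.675], "prenatal")
  ## score 0 is the earliest event: exp(intercept)
  t0 <- event_day(p, tibble::tibble(label = "first", score = 0))
  expect_equal(t0$post_conception_day, exp(p$intercept), tolerance = 1e-12)
})

test_that("the cortical-neurogenesis interaction adds 0.263 for non-glires", {
  p <- species_params(160, 80)
  ev <- tibble::tibble(label = "cn", score = 0.3, cortical_neurogenesis = 1)
  d1 <- event_day(p, ev, non_glire = TRUE)
  d0 <- event_day(p, ev, non_glire = FALSE)
  expect_equal(
    log(d1$post_conception_day) - log(d0$post_conception_day),
    0.263,
    tolerance = 1e-12
  )
})

test_that("the human birth event score is 0.695 and inversions round trip", {
  s <- birth_event_score(275, 1330)
  expect_equal(round(s, 3), 0.695)
  ## round trip through event_day: signed day 0 at the birth score
  p <- species_params(275, 1330)
  td <- event_day(p, tibble::tibble(label = "birth", score = s))
  expect_equal(td$signed_day, 0, tolerance = 1e-10)
  ## fixed-intercept inversion returns observed gestation at the own score
  expect_equal(
    gestation_for_event_score(s, 1330, observed_gestation = 275),
    275,
    tolerance = 1e-10
  )
  ## self-consistent mode is the exact algebraic inverse
  for (sc in c(0.1, 0.5, 0.9)) {
    g <- gestation_for_event_score(sc, 500, mode = "self_consistent")
    expect_equal(birth_event_score(g, 500), sc, tolerance = 1e-10)
  }
})

test_that("birth score is monotone in brain mass and gestation", {
  masses <- c(10, 100, 1000, 5000)
  expect_true(all(diff(birth_event_score(275, masses)) < 0))
  gests <- c(100, 200, 300, 400)
  expect_true(all(diff(birth_event_score(gests, 1000)) > 0))
  ## fixed point: gestation equal to exp(intercept) gives score 0
  g0 <- exp((1.241) / (1 - 0.368))
  expect_equal(birth_event_score(g0, 123), 0, tolerance = 1e-10)
})

test_that("great-ape birth scores give a ~322-day expected human gestation", {
  apes <- readr::read_csv(
    system.file("extdata", "great_apes_synthetic.csv", package = "altrix"),
    show_col_types = FALSE
  )
  sc <- birth_event_score(apes$gestation, apes$brain_mass)
  nonhuman <- sc[apes$species != "Homo sapiens"]
  expect_equal(round(range(nonhuman), 3), c(0.727, 0.756))
  g <- gestation_for_event_score(mean(nonhuman), 1330, observed_gestation = 275)
  expect_equal(g, 322, tolerance = 0.01)
})

test_that("hominin gestations: raw estimates, rescaling, error bands", {
  hom <- hominin_fixture()
  cfg <- neurodev_config()
  raw <- estimate_hominin_gestation(hom, cfg$growth_rate)
  expect_equal(raw$raw_mean[raw$species == "Ardipithecus ramidus"], 168)
  expect_equal(raw$raw_mean[raw$species == "Homo neanderthalensis"], 313)
  expect_true(all(raw$raw_min < raw$raw_mean & raw$raw_mean < raw$raw_max))
  expect_error(estimate_hominin_gestation(hom, -2), "positive")

  ## min-max rescale: endpoints exact, interior linear
  adj <- rescale_gestations(c(168, 240.5, 313), c(245, 275))
  expect_equal(adj[c(1, 3)], c(245, 275))
  expect_equal(adj[2], 260)
  expect_error(rescale_gestations(c(200, 200)), "distinct")

  ## multiplicative error propagation on random inputs
  set.seed(1)
  for (i in 1:20) {
    m <- runif(1, 100, 400)
    lo <- m * runif(1, 0.7, 1)
    hi <- m * runif(1, 1, 1.3)
    am <- runif(1, 200, 300)
    b <- propagate_gestation_error(m, lo, hi, am)
    expect_equal(b$adjusted_min, am * lo / m, tolerance = 1e-12)
    expect_equal(b$adjusted_max, am * hi / m, tolerance = 1e-12)
  }
  b0 <- propagate_gestation_error(100, 100, 100, 260)
  expect_equal(b0$adjusted_min, b0$adjusted_max)
})

test_that("ECV conversion modes are monotone and guarded", {
  expect_equal(ecv_to_brain_mass(400), 400)
  expect_equal(
    ecv_to_brain_mass(400, list(method = "power", a = 1.036, b = 1)),
    414.4
  )
  v <- ecv_to_brain_mass(c(100, 500, 1500), list(method = "power", a = 1.1, b = 0.98))
  expect_true(all(diff(v) > 0))
  expect_error(ecv_to_brain_mass(400, list(method = "power")), "coefficients")
  expect_error(ecv_to_brain_mass(-5), "> 0")
})

test_that("identical species produce no shifted events", {
  ss <- tibble::tibble(
    species = c("a", "b"), gestation = c(250, 250), brain_mass = c(400, 400)
  )
  sh <- classify_event_shifts(ss, fixture_event_table())
  expect_false(any(sh$shifts))
})

test_that("bracketing species shift exactly the strictly interior events", {
  ## construct two species whose birth scores are exactly 0.675 and 0.770
  g1 <- gestation_for_event_score(0.675, 1400, mode = "self_consistent")
  g2 <- gestation_for_event_score(0.770, 280, mode = "self_consistent")
  ss <- tibble::tibble(
    species = c("late", "early"),
    gestation = c(g1, g2),
    brain_mass = c(1400, 280)
  )
  sh <- classify_event_shifts(ss, fixture_event_table())
  expect_equal(attr(sh, "window"), c(0.675, 0.770), tolerance = 1e-9)
  ## boundary events (exactly 0.675 and 0.770) do not shift; interior do
  expect_equal(sum(sh$shifts), 11)
  expect_false(sh$shifts[sh$score == 0.675])
  expect_false(sh$shifts[sh$score == 0.77])
  expect_true(all(sh$shifts[sh$score > 0.675 & sh$score < 0.77]))
})

test_that("sign-flip and window characterizations agree on random inputs", {
  set.seed(42)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    ss <- tibble::tibble(
      species = paste0("s", 1:k),
      gestation = runif(k, 120, 400),
      brain_mass = exp(runif(k, 2, 8))
    )
    ev <- tibble::tibble(
      label = paste0("e", 1:40),
      score = runif(40)
    )
    ## classify_event_shifts aborts internally if the two characterizations
    ## disagree, so a silent return is the property under test
    sh <- classify_event_shifts(ss, ev)
    w <- attr(sh, "window")
    expect_equal(sh$shifts, ev$score > w[1] & ev$score < w[2])
  }
})

test_that("hominin fixture shifts all 13 landmark events under widest bands", {
  hg <- hominin_gestations(hominin_fixture(), neurodev_config())
  ss <- tibble::tibble(
    species = hg$species,
    gestation = hg$adjusted_mean,
    gestation_min = hg$adjusted_min,
    gestation_max = hg$adjusted_max,
    brain_mass = hg$brain_mass
  )
  sh_w <- classify_event_shifts(ss, fixture_event_table(), band = "widest")
  expect_true(all(sh_w$shifts))
  expect_equal(round(attr(sh_w, "window"), 3), c(0.674, 0.772))
  ## a full-size event table still shifts exactly the 13 landmark events
  sh215 <- classify_event_shifts(
    ss, fixture_event_table(n_filler = 202),
    band = "widest"
  )
  expect_equal(sum(sh215$shifts), 13)
  ## means-only and narrowest readings are strictly narrower
  sh_m <- classify_event_shifts(ss, fixture_event_table(), band = "mean")
  sh_n <- classify_event_shifts(ss, fixture_event_table(), band = "narrowest")
  expect_lt(sum(sh_m$shifts), 13)
  expect_lte(sum(sh_n$shifts), sum(sh_m$shifts))
})
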