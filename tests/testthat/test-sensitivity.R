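test_that("parameter sampling respects bounds and closed-form moments", {
  withr::with_seed(151, {
    # degenerate spec is a point mass
    d <- param_spec("tace_cost", "gamma", 5708, 5708, 5708)
    expect_equal(sample_param(d, 100), rep(5708, 100))

    # triangular mean (a + c + b) / 3
    tri <- param_spec("start_age", "triangular", 65, 60, 67)
    x <- sample_param(tri, 100000)
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - (60 + 65 + 67) / 3), 3 * se)
    expect_true(all(x >= 60 & x <= 67))

    # truncated gamma honours the printed cost bounds
    g <- param_spec("cost_tace", "gamma", 5708, 5500, 5800)
    xg <- sample_param(g, 2000)
    expect_true(all(xg >= 5500 & xg <= 5800))

    # beta on +/-10% bounds stays inside and centres near the mode
    b <- param_spec("p", "beta", 0.05, 0.045, 0.055)
    xb <- sample_param(b, 5000)
    expect_true(all(xb >= 0.045 & xb <= 0.055))
    expect_lt(abs(mean(xb) - 0.05), 0.001)

    ln <- param_spec("c", "lognormal", 4500, 2935, 10320)
    xl <- sample_param(ln, 2000)
    expect_true(all(xl >= 2935 & xl <= 10320))
  })
  expect_error(param_spec("bad", "gamma", 5, 10, 1), "min > max")
  expect_error(param_spec("bad", "gamma", 20, 1, 10), "mode outside")
})

test_that("quadrant classification follows the conservative axis rule", {
  pts <- data.frame(incremental_effect = c(1, 1, -1, 1),
                    incremental_cost = c(-1, -2, 1, 1))
  qf <- quadrant_fractions(pts)
  expect_equal(qf[["se_dominant"]], 0.5)
  expect_equal(sum(qf), 1)

  one <- data.frame(incremental_effect = 1, incremental_cost = -1)
  expect_equal(quadrant_fractions(one)[["se_dominant"]], 1)

  axis <- data.frame(incremental_effect = 0, incremental_cost = -1)
  expect_equal(quadrant_fractions(axis)[["se_dominant"]], 0)

  set.seed(161)
  rnd <- data.frame(incremental_effect = rnorm(500), incremental_cost = rnorm(500))
  expect_equal(sum(quadrant_fractions(rnd)), 1)

  expect_error(quadrant_fractions(pts[0, ]), "empty")
})

test_that("degenerate PSA collapses onto the base case", {
  base <- run_weighted_cea(base_model_set)$ce
  psa <- run_psa(base_model_set, specs = degenerate_specs(base_model_set),
                 n_draws = 10, seed = 7)
  expect_equal(psa$points$incremental_cost, rep(base$incremental_cost, 10))
  expect_equal(psa$points$incremental_effect, rep(base$incremental_effect, 10))
  expect_true(psa$dominant_fraction %in% c(0, 1))
  expect_equal(psa$n_rejected, 0)
})

test_that("PSA summaries are reproducible from the seed", {
  a <- run_psa(base_model_set, n_draws = 30, seed = 17)
  b <- run_psa(base_model_set, n_draws = 30, seed = 17)
  expect_identical(a$points, b$points)
  expect_identical(a$quadrant_fractions, b$quadrant_fractions)
  expect_identical(a$ci_cost, b$ci_cost)
  d <- run_psa(base_model_set, n_draws = 30, seed = 18)
  expect_false(identical(a$points, d$points))
})

test_that("percentile intervals cover the base case under symmetric draws", {
  base <- run_weighted_cea(base_model_set)$ce
  # symmetric triangular uncertainty on two cost items only
  specs <- list(
    param_spec("cost_ablation", "triangular", 4895, 4795, 4995,
               target = list(type = "cost", field = "ablation")),
    param_spec("cost_tace", "triangular", 5708, 5608, 5808,
               target = list(type = "cost", field = "tace"))
  )
  names(specs) <- c("cost_ablation", "cost_tace")
  psa <- run_psa(base_model_set, specs = specs, n_draws = 200, seed = 19)
  expect_gte(base$incremental_cost, psa$ci_cost[1])
  expect_lte(base$incremental_cost, psa$ci_cost[2])
  expect_gte(base$incremental_effect, psa$ci_effect[1] - 1e-9)
  expect_lte(base$incremental_effect, psa$ci_effect[2] + 1e-9)
})

test_that("one-way DSA ranks structure sensibly", {
  specs <- default_param_specs(base_model_set)
  # keep the run small: discount, one degenerate cost, two transitions
  degen <- param_spec("cost_tace", "gamma", 5708, 5708, 5708,
                      target = list(type = "cost", field = "tace"))
  sub <- c(specs["discount_rate"], list(cost_tace = degen),
           specs["p_death_bondy_ablation"], specs["p_death_soc_tace"])
  dsa <- one_way_dsa(base_model_set, sub)
  expect_false(any(dsa$failed))
  # a point-mass parameter has zero output range
  expect_equal(dsa$cost_range[dsa$parameter == "cost_tace"], 0)
  expect_equal(dsa$effect_range[dsa$parameter == "cost_tace"], 0)
  # a transition probability tops the tornado among these entries
  expect_match(dsa$parameter[1], "^(p_death|discount)")

  # discounting 0% vs 6%: life-years strictly larger at 0% for both groups
  ms0 <- base_model_set; ms0$discount <- discount_spec(annual_rate = 0)
  ms6 <- base_model_set; ms6$discount <- discount_spec(annual_rate = 0.06)
  r0 <- run_weighted_cea(ms0); r6 <- run_weighted_cea(ms6)
  expect_gt(r0$totals$bondy$total_life_years, r6$totals$bondy$total_life_years)
  expect_gt(r0$totals$soc$total_life_years, r6$totals$soc$total_life_years)
})

test_that("sensitivity artefacts export round-trip", {
  psa <- run_psa(base_model_set, specs = degenerate_specs(base_model_set),
                 n_draws = 5, seed = 3)
  pp <- tempfile(fileext = ".csv"); sp <- tempfile(fileext = ".json")
  export_sensitivity(psa = psa, points_path = pp, summary_path = sp)
  pts <- read.csv(pp)
  expect_identical(names(pts),
                   c("draw", "incremental_cost_eur", "incremental_effect_lyg"))
  expect_equal(nrow(pts), 5)
  js <- jsonlite::read_json(sp)
  expect_equal(js$n_draws, 5)
  expect_equal(js$seed, 3)
})
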