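test_that("transition matrices are valid and validation names bad rows", {
  for (g in c("bondy", "soc")) {
    for (p in base_model_set$params[[g]]) {
      M <- build_transition_matrix(p)
      expect_equal(rowSums(M), setNames(rep(1, 8), rownames(M)), tolerance = 1e-12)
      expect_true(all(M >= 0 & M <= 1))
      expect_equal(unname(M["death", ]), c(rep(0, 7), 1))
    }
  }
  m <- build_arm_model(base_model_set$params$bondy$ablation)
  m$matrix["initial_treatment", "death"] <- 0.5  # breaks the row sum
  expect_error(run_cohort_model(m), "initial_treatment")
})

test_that("occupancy is conserved and death absorption is monotone", {
  for (g in c("bondy", "soc")) {
    for (p in base_model_set$params[[g]]) {
      res <- run_cohort_model(build_arm_model(p, base_model_set$costs),
                              base_model_set$discount)
      expect_equal(rowSums(res$trace), rep(1, nrow(res$trace)), tolerance = 1e-9)
      expect_true(all(diff(res$trace[, "death"]) >= -1e-12))
      expect_lte(res$discounted_life_years, res$undiscounted_life_years)
      expect_lte(res$discounted_cost, res$undiscounted_cost)
    }
  }
})

test_that("the single-transient-state limit equals the geometric closed form", {
  # sorafenib structure with stop probability 0 keeps all surviving mass in
  # one state with constant per-cycle death probability p
  p <- 0.05
  par <- arm_params("sorafenib", p_death = p, p_retreat = 0)
  model <- build_arm_model(par, cost_schedule())
  # zero discounting: life-years are 0.25 * sum_{t=0}^{79} (1-p)^t
  d0 <- discount_spec(annual_rate = 0)
  res0 <- run_cohort_model(model, d0)
  expect_equal(res0$discounted_life_years,
               0.25 * sum((1 - p)^(0:79)), tolerance = 1e-9)
  # 3% discounting: geometric series in (1-p) * (1.03)^(-1/4)
  d3 <- discount_spec(annual_rate = 0.03)
  res3 <- run_cohort_model(model, d3)
  x <- (1 - p) * (1.03)^(-1/4)
  expect_equal(res3$discounted_life_years,
               0.25 * (1 - x^80) / (1 - x), tolerance = 1e-9)
})

test_that("a cohort starting in death accrues nothing", {
  model <- build_arm_model(base_model_set$params$bondy$ablation,
                           base_model_set$costs)
  start <- c(rep(0, 7), 1)
  res <- run_cohort_model(model, base_model_set$discount, start = start)
  expect_equal(res$discounted_cost, 0)
  expect_equal(res$discounted_life_years, 0)
})

test_that("results are monotone in the discount rate", {
  model <- build_arm_model(base_model_set$params$soc$tace, base_model_set$costs)
  res <- lapply(c(0, 0.03, 0.06), function(r) {
    run_cohort_model(model, discount_spec(annual_rate = r))
  })
  ly <- vapply(res, `[[`, numeric(1), "discounted_life_years")
  co <- vapply(res, `[[`, numeric(1), "discounted_cost")
  expect_true(all(diff(ly) < 0))
  expect_true(all(diff(co) < 0))
})

test_that("half-cycle correction lowers accumulated life-years", {
  model <- build_arm_model(base_model_set$params$soc$ablation,
                           base_model_set$costs)
  full <- run_cohort_model(model, base_model_set$discount)
  half <- run_cohort_model(model, base_model_set$discount, half_cycle = TRUE)
  expect_lt(half$discounted_life_years, full$discounted_life_years)
})

test_that("calibration hits its targets and degenerates correctly", {
  disc <- discount_spec()
  # maximum achievable life-years (no deaths): the full discounted annuity
  x <- (1.03)^(-1/4)
  max_ly <- 0.25 * (1 - x^80) / (1 - x)
  p <- calibrate_transitions("ablation", target_life_years = max_ly,
                             discount = disc, ly_discounted = TRUE)
  expect_lt(p$p_death, 1e-4)

  # round trip on a feasible discounted target
  p2 <- calibrate_transitions("tace", target_life_years = 7.4,
                              target_cost = 25000, discount = disc,
                              structure = arm_params("tace", 0, p_transplant = 0.004,
                                                     p_convert = 0.01),
                              ly_discounted = TRUE)
  res2 <- run_cohort_model(build_arm_model(p2), disc)
  expect_equal(res2$discounted_life_years, 7.4, tolerance = 0.005)
  expect_equal(res2$discounted_cost, 25000, tolerance = 0.005 * 25000)

  # unreachable target errors and reports the bracket
  expect_error(
    calibrate_transitions("ablation", target_life_years = 30, discount = disc),
    "achievable range"
  )
})

test_that("bisection agrees with a brute-force grid search", {
  disc <- discount_spec()
  target <- 9
  ly_at <- function(q) {
    run_cohort_model(build_arm_model(arm_params("ablation", q)), disc)$undiscounted_life_years
  }
  p <- calibrate_transitions("ablation", target_life_years = target, discount = disc)
  grid <- seq(0, 0.2, by = 1e-4)
  best <- grid[which.min(abs(vapply(grid, ly_at, numeric(1)) - target))]
  expect_lt(abs(p$p_death - best), 1e-4)
})

test_that("weighting arms reproduces totals and respects degenerate weights", {
  w <- first_line_weights("bondy")
  per_patient <- list(
    resection = list(cost = 1000, life_years = 2),
    ablation = list(cost = 2000, life_years = 4),
    tace = list(cost = 3000, life_years = 6),
    sorafenib = list(cost = 4000, life_years = 8)
  )
  tot <- weight_arms(per_patient, w)
  expect_equal(tot$total_cost, sum(w * c(1000, 2000, 3000, 4000)))
  expect_equal(tot$total_life_years, sum(w * c(2, 4, 6, 8)))

  all_on_one <- c(resection = 0, ablation = 1, tace = 0, sorafenib = 0)
  t1 <- weight_arms(per_patient, all_on_one)
  expect_equal(t1$total_cost, 2000)
  expect_equal(t1$total_life_years, 4)

  expect_error(weight_arms(per_patient[1:3], w), "missing arm")
})

test_that("ICER classification covers dominance, ratios and edge cases", {
  mk <- function(c, e) list(cost = c, life_years = e)
  expect_identical(icer(mk(-7288, 0.8), mk(0, 0))$label, "dominant")
  expect_identical(icer(mk(1000, -2), mk(0, 0))$label, "dominated")
  r <- icer(mk(1000, 2), mk(0, 0))
  expect_identical(r$label, "ratio")
  expect_equal(r$icer, 500)
  expect_identical(icer(mk(0, 0), mk(0, 0))$label, "equivalent")
  expect_identical(icer(mk(-10, 0), mk(0, 0))$label, "dominant")
  expect_identical(icer(mk(10, 0), mk(0, 0))$label, "dominated")
})

test_that("euro-to-dollar conversion follows the display convention", {
  expect_equal(to_usd(18205), 20026)
  expect_equal(to_usd(7288), 8017)
  expect_equal(to_usd(0), 0)
  expect_equal(to_usd(-7288), -8017)
  expect_equal(to_usd(18205, display = FALSE), 20025.5)
})

test_that("the calibrated base case reproduces its cost targets", {
  cea <- run_weighted_cea(base_model_set)
  ref <- base_case_reference()
  expect_equal(cea$totals$bondy$total_cost, ref$printed_totals$bondy$cost,
               tolerance = 0.005)
  expect_equal(cea$totals$soc$total_cost, ref$printed_totals$soc$cost,
               tolerance = 0.005)
  expect_identical(cea$ce$label, "dominant")
  expect_gt(cea$ce$incremental_effect, 0)
  expect_lt(cea$ce$incremental_cost, 0)
})
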