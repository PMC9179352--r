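test_that("product-limit estimator matches hand-computed values", {
  km <- km_fit(c(10, 20, 30), c(TRUE, TRUE, TRUE))
  expect_equal(km$survival, c(2/3, 1/3, 0), tolerance = 1e-12)
  expect_equal(km$median, 20)
  expect_equal(km$n_risk, c(3, 2, 1))

  # KM on uncensored data equals the empirical survival function
  set.seed(121)
  tt <- rexp(500, 0.05)
  km2 <- km_fit(tt, rep(TRUE, 500))
  emp <- vapply(km2$times, function(u) mean(tt > u), numeric(1))
  expect_equal(km2$survival, emp, tolerance = 1e-12)

  allc <- km_fit(c(5, 10, 15), c(FALSE, FALSE, FALSE))
  expect_true(all(allc$survival == 1))
  expect_true(is.na(allc$median))

  expect_error(km_fit(numeric(0), logical(0)), "empty")
})

test_that("KM median recovers the generating exponential median", {
  set.seed(122)
  tt <- rexp(100000, log(2) / 35)
  km <- km_fit(tt, rep(TRUE, length(tt)))
  expect_gt(km$median, 34.4)
  expect_lt(km$median, 35.6)
})

test_that("log-rank test matches the direct hypergeometric computation", {
  # identical samples: statistic 0, p = 1
  tt <- c(3, 6, 9, 12); ev <- c(TRUE, TRUE, FALSE, TRUE)
  r0 <- logrank_test(tt, ev, tt, ev)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1, tolerance = 1e-12)

  # small worked set against the by-hand oracle
  tA <- c(1, 2); eA <- c(TRUE, TRUE)
  tB <- c(3, 4); eB <- c(TRUE, TRUE)
  r <- logrank_test(tA, eA, tB, eB)
  expect_equal(r$statistic, logrank_by_hand(tA, eA, tB, eB), tolerance = 1e-9)

  set.seed(123)
  for (k in 1:5) {
    tA <- round(rexp(12, 0.1), 2); eA <- runif(12) < 0.8
    tB <- round(rexp(15, 0.2), 2); eB <- runif(15) < 0.8
    r <- logrank_test(tA, eA, tB, eB)
    expect_equal(r$statistic, logrank_by_hand(tA, eA, tB, eB), tolerance = 1e-9)
  }

  expect_error(logrank_test(numeric(0), logical(0), tt, ev), "non-empty")
  expect_error(logrank_test(c(1, 2), c(FALSE, FALSE), c(3, 4), c(FALSE, FALSE)),
               "events")
})

test_that("a threefold hazard ratio is detected with high power", {
  set.seed(124)
  for (k in 1:3) {
    tA <- rexp(500, 0.02); tB <- rexp(500, 0.06)
    r <- logrank_test(tA, rep(TRUE, 500), tB, rep(TRUE, 500))
    expect_lt(r$p_value, 0.001)
  }
})

test_that("parametric fits recover their closed forms and true parameters", {
  f <- fit_parametric(c(10, 20, 30), c(TRUE, TRUE, TRUE), "exponential")
  expect_equal(unname(f$params["rate"]), 0.05, tolerance = 1e-12)
  expect_equal(f$median_months, log(2) / 0.05, tolerance = 1e-12)
  expect_equal(f$bic, 1 * log(3) - 2 * f$loglik, tolerance = 1e-12)

  # censoring does not bias the exponential MLE
  set.seed(131)
  lam <- 0.04; n <- 10000
  tt <- rexp(n, lam)
  f_full <- fit_parametric(tt, rep(TRUE, n), "exponential")
  cen <- pmin(tt, quantile(tt, 0.5))
  ev <- tt <= quantile(tt, 0.5)
  f_cens <- fit_parametric(cen, ev, "exponential")
  se_full <- lam / sqrt(n)
  se_cens <- lam / sqrt(sum(ev))
  expect_lt(abs(f_full$params[["rate"]] - lam), 3 * se_full)
  expect_lt(abs(f_cens$params[["rate"]] - lam), 3 * se_cens)

  # Weibull on exponential data: shape compatible with 1
  fw <- fit_parametric(tt, rep(TRUE, n), "weibull")
  expect_lt(abs(fw$params[["shape"]] - 1), 0.03)
  expect_gt(fw$median_months, 0)

  fg <- fit_parametric(tt, rep(TRUE, n), "gompertz")
  expect_lt(abs(fg$params[["shape"]]), 0.005)

  expect_error(fit_parametric(c(1, 2), c(FALSE, FALSE), "exponential"),
               "at least one event")
})

test_that("BIC selection prefers parsimony with deterministic tie-breaks", {
  set.seed(141)
  tt <- rexp(2000, 0.05); ev <- rep(TRUE, 2000)
  fits <- lapply(c("exponential", "weibull", "gompertz"),
                 function(fam) fit_parametric(tt, ev, fam))
  best <- select_by_bic(fits)
  expect_identical(best$family, "exponential")
  expect_identical(select_by_bic(fits[2]), fits[[2]])

  # equal BIC: fewer parameters wins
  a <- fits[[1]]; b <- fits[[2]]
  b$bic <- a$bic
  expect_identical(select_by_bic(list(b, a))$family, "exponential")

  short <- fit_parametric(tt[1:100], ev[1:100], "exponential")
  expect_error(select_by_bic(list(a, short)), "mismatched n")
})

test_that("median, rate and cycle-probability conversions are exact", {
  expect_equal(median_to_rate(35), log(2) / 35, tolerance = 1e-15)
  expect_equal(rate_to_cycle_prob(median_to_rate(35), 3), 0.0577, tolerance = 1e-3)
  expect_equal(rate_to_cycle_prob(median_to_rate(12), 3), 1 - 2^(-1/4),
               tolerance = 1e-12)
  expect_equal(rate_to_cycle_prob(0, 3), 0)
  expect_error(median_to_rate(0), "positive")
  # round trip to machine precision
  for (m in c(4, 12, 35, 55)) {
    expect_equal(log(2) / median_to_rate(m), m, tolerance = 1e-12)
  }
  # strictly increasing in both arguments
  expect_gt(rate_to_cycle_prob(0.03, 3), rate_to_cycle_prob(0.02, 3))
  expect_gt(rate_to_cycle_prob(0.03, 6), rate_to_cycle_prob(0.03, 3))
})

test_that("survival artefacts export to CSV and JSON", {
  km <- km_fit(c(10, 20, 30), c(TRUE, TRUE, TRUE))
  f <- fit_parametric(c(10, 20, 30), c(TRUE, TRUE, TRUE), "exponential")
  cp <- tempfile(fileext = ".csv"); fp <- tempfile(fileext = ".json")
  export_survival(curve = km, fit = f, curve_path = cp, fit_path = fp)
  tab <- read.csv(cp)
  expect_identical(names(tab), c("time", "n_at_risk", "n_events", "survival"))
  js <- jsonlite::read_json(fp)
  expect_identical(js$family, "exponential")
  expect_equal(js$params$rate, 0.05, tolerance = 1e-12)
})
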