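test_that("propensity model recovers a known assignment rule", {
  # note: the assignment seed must differ from the cohort seed, otherwise
  # the assignment uniforms replay the stream that generated the covariates
  set.seed(172)
  n <- 5000
  coh <- generate_cohort(bondy_profile(n), seed = 71)
  # reassign group by a logistic rule on (centred) age only
  beta_age <- 0.08
  eta <- -0.5 + beta_age * (coh$age - 66)
  coh$group <- factor(ifelse(runif(n) < plogis(eta), "bondy", "soc"),
                      c("bondy", "soc"))
  pm <- estimate_propensity(coh)
  est <- pm$coefficients[["age"]]
  se <- summary(pm$model)$coefficients["age", "Std. Error"]
  expect_lt(abs(est - beta_age), 3 * se)
  # a covariate with no role in assignment has a near-null coefficient
  z_bilobar <- summary(pm$model)$coefficients["bilobarTRUE", "z value"]
  expect_lt(abs(z_bilobar), 4)
  expect_true(all(pm$scores > 0 & pm$scores < 1))
})

test_that("propensity estimation rejects degenerate input", {
  coh <- generate_cohort(bondy_profile(100), seed = 72)
  expect_error(estimate_propensity(coh), "both groups")
  mixed <- rbind(generate_cohort(bondy_profile(100), seed = 72),
                 generate_cohort(soc_profile(100), seed = 73))
  holey <- inject_missingness(mixed, c(afp_cat = 0.3), seed = 74)
  expect_error(estimate_propensity(holey), "impute_missing")
})

test_that("optimal matching beats greedy on the worked example", {
  # logits 0.2, 0.8 vs 0.25, 0.6, 0.9: optimum pairs (0.2, 0.25) and
  # (0.8, 0.9) with total distance 0.15; greedy from 0.8 would take 0.6
  trt <- setNames(plogis(c(0.2, 0.8)), c("t1", "t2"))
  ctl <- setNames(plogis(c(0.25, 0.6, 0.9)), c("c1", "c2", "c3"))
  m <- match_optimal(trt, ctl)
  expect_equal(nrow(m$pairs), 2)
  expect_equal(m$total_distance, 0.15, tolerance = 1e-9)
  expect_identical(m$pairs$control_id[m$pairs$treated_id == "t1"], "c1")
  expect_identical(m$pairs$control_id[m$pairs$treated_id == "t2"], "c3")
})

test_that("matching respects 1:1-without-replacement cardinality", {
  set.seed(81)
  trt <- setNames(runif(272, 0.2, 0.8), sprintf("t%03d", 1:272))
  ctl <- setNames(runif(557, 0.2, 0.8), sprintf("c%03d", 1:557))
  m <- match_optimal(trt, ctl)
  expect_equal(nrow(m$pairs), 272)
  expect_false(any(duplicated(m$pairs$control_id)))
  expect_false(any(duplicated(m$pairs$treated_id)))

  # identical score lists give zero total distance
  s <- setNames(runif(20, 0.3, 0.7), sprintf("x%02d", 1:20))
  s2 <- s; names(s2) <- sprintf("y%02d", 1:20)
  expect_equal(match_optimal(s, s2)$total_distance, 0, tolerance = 1e-12)

  # a caliper never increases the pair count
  m_cal <- match_optimal(trt, ctl, caliper = 0.01)
  expect_lte(nrow(m_cal$pairs), nrow(m$pairs))
  expect_true(all(m_cal$pairs$distance <= 0.01))
  expect_setequal(c(m_cal$pairs$treated_id, m_cal$unmatched_treated), names(trt))

  expect_warning(m0 <- match_optimal(setNames(numeric(0), character(0)), ctl),
                 "empty")
  expect_equal(nrow(m0$pairs), 0)
})

test_that("assignment solver matches exhaustive enumeration on small instances", {
  set.seed(91)
  for (trial in 1:200) {
    nt <- sample(1:5, 1); nc <- nt + sample(0:(5 - nt), 1)
    cost <- matrix(runif(nt * nc), nt, nc)
    idx <- lsap_solve(cost)
    total <- sum(cost[cbind(seq_len(nt), idx)])
    expect_equal(total, brute_force_assignment(cost), tolerance = 1e-12)
  }
})

test_that("multiple imputation preserves observed structure", {
  coh <- rbind(generate_cohort(bondy_profile(2000), seed = 101),
               generate_cohort(soc_profile(2000), seed = 102))
  done <- impute_missing(coh, m = 3, seed = 103)
  expect_length(done, 3)
  expect_true(all(vapply(done, identical, logical(1), coh)))  # nothing missing

  holey <- inject_missingness(coh, c(afp_cat = 0.2), seed = 104)
  imp <- impute_missing(holey, m = 5, seed = 105)
  expect_length(imp, 5)
  expect_false(anyNA(imp[[1]]$afp_cat))
  # within-group marginal of the completed data close to the observed one
  for (g in c("bondy", "soc")) {
    obs <- prop.table(table(holey$afp_cat[holey$group == g]))
    got <- prop.table(table(imp[[1]]$afp_cat[imp[[1]]$group == g]))
    expect_lt(max(abs(obs - got)), 0.03)
  }
  expect_identical(impute_missing(holey, 1, seed = 9)[[1]],
                   impute_missing(holey, 1, seed = 9)[[1]])

  allgone <- holey
  allgone$child_pugh <- factor(NA, levels(holey$child_pugh))
  expect_error(impute_missing(allgone, 1, seed = 1), "child_pugh")
})

test_that("balance diagnostics behave under null, identity and imbalance", {
  set.seed(111)
  coh <- rbind(generate_cohort(bondy_profile(1500), seed = 112),
               generate_cohort(soc_profile(1500), seed = 113))
  # same marginal generator for a key covariate: matched SMDs small
  pm <- estimate_propensity(coh)
  trt <- pm$scores[coh$group == "bondy"]
  ctl <- pm$scores[coh$group == "soc"]
  m <- match_optimal(trt, ctl)
  bal <- balance_table(coh, m)
  expect_true(all(c("smd_pre", "smd_post") %in% names(bal)))
  expect_lt(max(abs(bal$smd_post[bal$covariate == "bilobar"])), 0.1)

  # identical groups: SMD exactly zero everywhere
  twin <- coh[coh$group == "bondy", ]
  twin2 <- twin
  twin2$group <- factor("soc", c("bondy", "soc"))
  twin2$id <- paste0("s-", twin2$id)
  both <- rbind(twin, twin2)
  pairs0 <- match_optimal(setNames(rep(0.5, nrow(twin)), twin$id),
                          setNames(rep(0.5, nrow(twin2)), twin2$id))
  bal0 <- balance_table(both, pairs0)
  expect_true(all(bal0$smd_pre == 0))
  expect_true(all(bal0$smd_post == 0))

  # constructed imbalance shrinks after matching; the control reservoir must
  # exceed the treated side so the optimal match can select closer controls
  imb <- rbind(generate_cohort(bondy_profile(400), seed = 114),
               generate_cohort(soc_profile(1500), seed = 115))
  imb$age[imb$group == "bondy"] <- imb$age[imb$group == "bondy"] + 8
  pmi <- estimate_propensity(imb)
  mi <- match_optimal(pmi$scores[imb$group == "bondy"],
                      pmi$scores[imb$group == "soc"])
  bi <- balance_table(imb, mi)
  age_row <- bi[bi$covariate == "age", ]
  expect_gt(abs(age_row$smd_pre), abs(age_row$smd_post))
})
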