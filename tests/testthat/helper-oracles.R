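# Shared fixtures and independent oracles.

# Built once per test run; both are deterministic.
fx <- matched_fixture()
base_model_set <- calibrate_base_model()

# Brute-force minimum-cost 1:1 assignment by exhaustive recursion with
# pruning; independent of the package's augmenting-path solver.
brute_force_assignment <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  stopifnot(nr <= nc)
  best <- Inf
  recurse <- function(row, used, acc) {
    if (acc >= best) return()
    if (row > nr) {
      best <<- acc
      return()
    }
    for (j in seq_len(nc)) {
      if (!used[j]) {
        used[j] <- TRUE
        recurse(row + 1, used, acc + cost[row, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1, logical(nc), 0)
  best
}

# Two-sample log-rank chi-square by direct summation of the hypergeometric
# terms at each distinct event time.
logrank_by_hand <- function(tA, eA, tB, eB) {
  time <- c(tA, tB); ev <- c(eA, eB)
  grp <- rep(c(0, 1), c(length(tA), length(tB)))
  ts <- sort(unique(time[ev == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk); nA <- sum(at_risk & grp == 0)
    d <- sum(ev == 1 & time == t); dA <- sum(ev == 1 & time == t & grp == 0)
    O <- O + dA
    E <- E + d * nA / n
    if (n > 1) V <- V + d * (nA / n) * (1 - nA / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# A tiny cohort data frame with explicit fields, for staging unit tests.
mini_patient <- function(n_tumors = "1", mm = 18, child = "A", vi = FALSE,
                         ps = 0L, first_line = "ablation", group = "bondy") {
  mm_cat <- if (mm <= 30) "le30" else if (mm <= 60) "30to60" else "gt60"
  data.frame(
    id = "p1", group = factor(group, c("bondy", "soc")), age = 65,
    male = TRUE, comorbidity_gt1 = FALSE,
    aetiology = factor("alcohol", c("alcohol", "hcv", "hbv", "nash", "other")),
    child_pugh = factor(child, c("A", "B", "C")),
    portal_htn = FALSE,
    afp_cat = factor("le100", c("le100", "100to1000", "gt1000")),
    n_tumors_cat = factor(n_tumors, c("1", "2_3", "ge4")),
    largest_mm = mm,
    largest_mm_cat = factor(mm_cat, c("le30", "30to60", "gt60")),
    bilobar = FALSE, vascular_invasion = vi, performance_status = ps,
    first_line = factor(first_line, c("resection", "ablation", "tace", "sorafenib")),
    time_months = 12, event = TRUE,
    stringsAsFactors = FALSE
  )
}

# Degenerate (point-mass) copies of the default parameter specifications.
degenerate_specs <- function(model_set) {
  specs <- default_param_specs(model_set)
  lapply(specs, function(sp) {
    sp$min <- sp$mode; sp$max <- sp$mode
    sp
  })
}
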