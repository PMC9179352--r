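#' @useDynLib ablateCEA, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats glm binomial qnorm pnorm qexp rexp runif quantile
#'   rbinom sd complete.cases coef pchisq uniroot rgamma rbeta rlnorm optimize
#' @importFrom utils read.csv write.csv head
NULL

# Factor level sets used throughout the package. Order matters: the first
# level is the reference level in the propensity model.
.levels <- list(
  group          = c("bondy", "soc"),
  aetiology      = c("alcohol", "hcv", "hbv", "nash", "other"),
  child_pugh     = c("A", "B"),
  afp_cat        = c("le100", "100to1000", "gt1000"),
  n_tumors_cat   = c("1", "2_3", "ge4"),
  largest_mm_cat = c("le30", "30to60", "gt60"),
  first_line     = c("resection", "ablation", "tace", "sorafenib"),
  stage          = c("very_early", "early", "intermediate", "advanced")
)

# Declared patient-table column order (also the cohort CSV layout).
.patient_cols <- c(
  "id", "group", "age", "male", "comorbidity_gt1", "aetiology", "child_pugh",
  "portal_htn", "afp_cat", "n_tumors_cat", "largest_mm", "largest_mm_cat",
  "bilobar", "vascular_invasion", "performance_status", "first_line",
  "time_months", "event"
)

# The eleven covariates the propensity model matches on; also the set of
# maskable fields for missingness injection.
.matching_covariates <- c(
  "age", "male", "comorbidity_gt1", "aetiology", "child_pugh", "portal_htn",
  "afp_cat", "vascular_invasion", "n_tumors_cat", "largest_mm_cat", "bilobar"
)

.chk_probs <- function(p, field) {
  if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop(sprintf("configuration error: probabilities for '%s' must be non-negative and sum to 1 (got sum %.12f)",
                 field, sum(p)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Cohort generation profile
#'
#' Bundles everything [generate_cohort()] needs: cohort size, covariate
#' marginals, the BCLC stage distribution, the stage-conditional first-line
#' allocation policy, per-arm median overall survivals and the administrative
#' censoring horizon. `bondy_profile()` and `soc_profile()` return the shipped
#' defaults reproducing the matched two-group case mix (extended-ablation
#' centre vs standard of care).
#'
#' @param n cohort size (non-negative integer).
#' @param group `"bondy"` or `"soc"`.
#' @param covariate_marginals named list of named probability vectors for the
#'   categorical covariates (`male`, `comorbidity_gt1`, `aetiology`,
#'   `child_pugh`, `portal_htn`, `afp_cat`, `n_tumors_cat`, `largest_mm_cat`,
#'   `bilobar`). Each vector must sum to 1 within 1e-9.
#' @param stage_distribution named probability vector over the four BCLC
#'   stages.
#' @param allocation_policy matrix (stages x arms) of first-line treatment
#'   probabilities per stage; rows must sum to 1.
#' @param survival_medians named vector, median overall survival in months for
#'   each first-line arm in this group; strictly positive.
#' @param censor_horizon_months administrative censoring bound (default 84
#'   months, i.e. 7 years).
#' @param missing_rate named vector of per-covariate missingness
#'   probabilities (default: none missing).
#' @param age_mean,age_sd parameters of the truncated-normal age distribution
#'   (truncated to 18--95 years).
#' @return an object of class `cohort_profile`.
#' @export
cohort_profile <- function(n, group,
                           covariate_marginals,
                           stage_distribution,
                           allocation_policy,
                           survival_medians,
                           censor_horizon_months = 84,
                           missing_rate = NULL,
                           age_mean = 66, age_sd = 11) {
  group <- match.arg(group, .levels$group)
  stopifnot(length(n) == 1, n >= 0, n == round(n))
  for (f in names(covariate_marginals)) .chk_probs(covariate_marginals[[f]], f)
  .chk_probs(stage_distribution, "stage_distribution")
  for (s in rownames(allocation_policy)) {
    .chk_probs(allocation_policy[s, ], paste0("allocation_policy[", s, "]"))
  }
  if (any(survival_medians <= 0)) {
    stop("configuration error: survival_medians must be strictly positive", call. = FALSE)
  }
  if (!is.null(missing_rate) && (any(missing_rate < 0) || any(missing_rate > 1))) {
    stop("configuration error: missing_rate must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    n = as.integer(n), group = group,
    covariate_marginals = covariate_marginals,
    stage_distribution = stage_distribution,
    allocation_policy = allocation_policy,
    survival_medians = survival_medians,
    censor_horizon_months = censor_horizon_months,
    missing_rate = missing_rate,
    age_mean = age_mean, age_sd = age_sd
  ), class = "cohort_profile")
}

.default_marginals <- function(group) {
  if (group == "bondy") {
    list(
      male            = c(`TRUE` = 214, `FALSE` = 52) / 266,
      comorbidity_gt1 = c(`TRUE` = 10, `FALSE` = 256) / 266,
      aetiology       = c(alcohol = 113, hcv = 89, hbv = 34, nash = 20, other = 10) / 266,
      child_pugh      = c(A = 243, B = 23) / 266,
      portal_htn      = c(`TRUE` = 154, `FALSE` = 112) / 266,
      afp_cat         = c(le100 = 189, `100to1000` = 48, gt1000 = 29) / 266,
      n_tumors_cat    = c(`1` = 165, `2_3` = 63, ge4 = 38) / 266,
      largest_mm_cat  = c(le30 = 115, `30to60` = 90, gt60 = 61) / 266,
      bilobar         = c(`TRUE` = 64, `FALSE` = 202) / 266
    )
  } else {
    list(
      male            = c(`TRUE` = 211, `FALSE` = 55) / 266,
      comorbidity_gt1 = c(`TRUE` = 19, `FALSE` = 247) / 266,
      aetiology       = c(alcohol = 117, hcv = 88, hbv = 32, nash = 22, other = 7) / 266,
      child_pugh      = c(A = 244, B = 22) / 266,
      portal_htn      = c(`TRUE` = 146, `FALSE` = 120) / 266,
      afp_cat         = c(le100 = 178, `100to1000` = 50, gt1000 = 38) / 266,
      n_tumors_cat    = c(`1` = 166, `2_3` = 61, ge4 = 39) / 266,
      largest_mm_cat  = c(le30 = 119, `30to60` = 93, gt60 = 54) / 266,
      bilobar         = c(`TRUE` = 64, `FALSE` = 202) / 266
    )
  }
}

.default_allocation <- function(group) {
  arms <- .levels$first_line
  stages <- .levels$stage
  m <- matrix(0, 4, 4, dimnames = list(stages, arms))
  if (group == "bondy") {
    m["very_early", ]   <- c(0, 16, 0, 0) / 16
    m["early", ]        <- c(0, 140, 14, 3) / 157
    m["intermediate", ] <- c(1, 21, 31, 2) / 55
    m["advanced", ]     <- c(0, 11, 2, 25) / 38
  } else {
    m["very_early", ]   <- c(0, 22, 0, 0) / 22
    m["early", ]        <- c(35, 35, 72, 4) / 146
    m["intermediate", ] <- c(0, 5, 50, 0) / 55
    m["advanced", ]     <- c(0, 2, 6, 35) / 43
  }
  m
}

#' @rdname cohort_profile
#' @export
bondy_profile <- function(n = 266) {
  cohort_profile(
    n, "bondy",
    covariate_marginals = .default_marginals("bondy"),
    stage_distribution = c(very_early = 16, early = 157, intermediate = 55, advanced = 38) / 266,
    allocation_policy = .default_allocation("bondy"),
    survival_medians = c(resection = 35, ablation = 35, tace = 12, sorafenib = 4)
  )
}

#' @rdname cohort_profile
#' @export
soc_profile <- function(n = 266) {
  cohort_profile(
    n, "soc",
    covariate_marginals = .default_marginals("soc"),
    stage_distribution = c(very_early = 22, early = 146, intermediate = 55, advanced = 43) / 266,
    allocation_policy = .default_allocation("soc"),
    survival_medians = c(resection = 55, ablation = 37, tace = 18, sorafenib = 9)
  )
}

.empty_cohort <- function() {
  df <- data.frame(
    id = character(0), group = factor(character(0), .levels$group),
    age = numeric(0), male = logical(0), comorbidity_gt1 = logical(0),
    aetiology = factor(character(0), .levels$aetiology),
    child_pugh = factor(character(0), .levels$child_pugh),
    portal_htn = logical(0),
    afp_cat = factor(character(0), .levels$afp_cat),
    n_tumors_cat = factor(character(0), .levels$n_tumors_cat),
    largest_mm = numeric(0),
    largest_mm_cat = factor(character(0), .levels$largest_mm_cat),
    bilobar = logical(0), vascular_invasion = logical(0),
    performance_status = integer(0),
    first_line = factor(character(0), .levels$first_line),
    time_months = numeric(0), event = logical(0),
    stringsAsFactors = FALSE
  )
  df[, .patient_cols]
}

# sample factor levels from a named probability vector
.rcat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic patient cohort
#'
#' Draws `profile$n` patients whose categorical covariates follow the profile
#' marginals, whose BCLC stage follows the profile stage distribution (with
#' vascular invasion equated to advanced stage and tumour number/size
#' constrained to be consistent with the stage), whose first-line treatment
#' follows the stage-conditional allocation policy, and whose overall-survival
#' times are exponential with rate `log(2) / median` for the patient's
#' (group, first-line) stratum, administratively censored at the horizon.
#'
#' Identical `(profile, seed)` pairs give identical cohorts.
#'
#' @param profile a [cohort_profile()].
#' @param seed integer seed.
#' @return a patient `data.frame` (one row per patient).
#' @export
generate_cohort <- function(profile, seed) {
  stopifnot(inherits(profile, "cohort_profile"))
  n <- profile$n
  if (n == 0) return(.empty_cohort())
  withr::with_seed(seed, {
    stage <- .rcat(n, profile$stage_distribution)
    vi <- stage == "advanced"
    ps <- rep(0L, n)

    mar <- profile$covariate_marginals
    n_cat <- character(n); mm <- numeric(n); mm_cat <- character(n)
    p_n <- mar$n_tumors_cat; p_s <- mar$largest_mm_cat
    for (i in seq_len(n)) {
      st <- stage[i]
      if (st == "very_early") {
        n_cat[i] <- "1"; mm[i] <- runif(1, 5, 20); mm_cat[i] <- "le30"
      } else if (st == "early") {
        # single tumour of any size (> 2 cm if <= 3 cm, else it would be very
        # early), or 2-3 nodules all <= 3 cm
        cells <- rbind(
          c("1", "le30"), c("1", "30to60"), c("1", "gt60"), c("2_3", "le30")
        )
        w <- p_n[cells[, 1]] * p_s[cells[, 2]]
        k <- sample(nrow(cells), 1, prob = w)
        n_cat[i] <- cells[k, 1]; mm_cat[i] <- cells[k, 2]
        mm[i] <- switch(mm_cat[i],
          le30 = runif(1, 20, 30), `30to60` = runif(1, 30, 60),
          gt60 = runif(1, 60, 100))
      } else if (st == "intermediate") {
        cells <- rbind(
          c("ge4", "le30"), c("ge4", "30to60"), c("ge4", "gt60"),
          c("2_3", "30to60"), c("2_3", "gt60")
        )
        w <- p_n[cells[, 1]] * p_s[cells[, 2]]
        k <- sample(nrow(cells), 1, prob = w)
        n_cat[i] <- cells[k, 1]; mm_cat[i] <- cells[k, 2]
        mm[i] <- switch(mm_cat[i],
          le30 = runif(1, 5, 30), `30to60` = runif(1, 30, 60),
          gt60 = runif(1, 60, 100))
      } else { # advanced: tumour burden unconstrained
        n_cat[i] <- .rcat(1, p_n); mm_cat[i] <- .rcat(1, p_s)
        mm[i] <- switch(mm_cat[i],
          le30 = runif(1, 5, 30), `30to60` = runif(1, 30, 60),
          gt60 = runif(1, 60, 100))
      }
    }

    child <- .rcat(n, mar$child_pugh)
    child[stage == "very_early"] <- "A"  # very early requires Child A

    # age: normal(mean, sd) truncated to [18, 95]
    lo <- pnorm(18, profile$age_mean, profile$age_sd)
    hi <- pnorm(95, profile$age_mean, profile$age_sd)
    age <- qnorm(runif(n, lo, hi), profile$age_mean, profile$age_sd)

    arm <- character(n)
    for (st in unique(stage)) {
      idx <- which(stage == st)
      arm[idx] <- .rcat(length(idx), profile$allocation_policy[st, ])
    }

    med <- profile$survival_medians[arm]
    t_event <- rexp(n, rate = log(2) / med)
    horizon <- profile$censor_horizon_months
    event <- t_event < horizon
    time_months <- pmin(t_event, horizon)

    df <- data.frame(
      id = sprintf("%s-%04d", profile$group, seq_len(n)),
      group = factor(profile$group, .levels$group),
      age = age,
      male = .rcat(n, mar$male) == "TRUE",
      comorbidity_gt1 = .rcat(n, mar$comorbidity_gt1) == "TRUE",
      aetiology = factor(.rcat(n, mar$aetiology), .levels$aetiology),
      child_pugh = factor(child, .levels$child_pugh),
      portal_htn = .rcat(n, mar$portal_htn) == "TRUE",
      afp_cat = factor(.rcat(n, mar$afp_cat), .levels$afp_cat),
      n_tumors_cat = factor(n_cat, .levels$n_tumors_cat),
      largest_mm = mm,
      largest_mm_cat = factor(mm_cat, .levels$largest_mm_cat),
      bilobar = .rcat(n, mar$bilobar) == "TRUE",
      vascular_invasion = vi,
      performance_status = ps,
      first_line = factor(arm, .levels$first_line),
      time_months = time_months,
      event = event,
      stringsAsFactors = FALSE
    )
    if (!is.null(profile$missing_rate) && any(profile$missing_rate > 0)) {
      df <- inject_missingness(df, profile$missing_rate,
                               seed = sample.int(.Machine$integer.max, 1))
    }
    df[, .patient_cols]
  })
}

# ---------------------------------------------------------------------------
# Deterministic matched fixture
# ---------------------------------------------------------------------------

# Spread k TRUE assignments (or category labels) evenly over n roster slots so
# that block-ordered structural fields (stage, arm) stay roughly independent
# of the unconstrained covariates.
.spread_positions <- function(n, k, taken = logical(n)) {
  free <- which(!taken)
  if (k == 0) return(integer(0))
  free[((seq_len(k) - 1) * length(free)) %/% k + 1]
}

.assign_categorical <- function(n, counts) {
  out <- character(n); taken <- logical(n)
  o <- order(-counts)
  for (lab in names(counts)[o]) {
    k <- counts[[lab]]
    if (k == 0) next
    pos <- .spread_positions(n, k, taken)
    out[pos] <- lab; taken[pos] <- TRUE
  }
  stopifnot(all(taken))
  out
}

# One group's fixture blueprint: per-stage tumour structure, stage x arm
# joint counts, covariate marginal counts. All counts are integers over 266.
.fixture_blueprint <- function(group) {
  if (group == "bondy") {
    list(
      n = 266,
      # stage blocks: very_early, early, intermediate, advanced
      stages = c(very_early = 16, early = 157, intermediate = 55, advanced = 38),
      # stage x arm joint counts (rows sum to stage totals)
      joint = rbind(
        very_early   = c(resection = 0, ablation = 16, tace = 0, sorafenib = 0),
        early        = c(0, 140, 14, 3),
        intermediate = c(1, 21, 31, 2),
        advanced     = c(0, 11, 2, 25)
      ),
      # tumour-structure plan per stage:
      #  early: n1 111 (sizes 53/43/15), n23 le30 46
      #  intermediate: ge4 38 (sizes 0/19/19), n23 30to60 10, n23 gt60 7
      #  advanced (VI): n1 43?? no: n1 38 (sizes 0/18/20)
      early_n1_sizes = c(le30 = 53, `30to60` = 43, gt60 = 15),
      early_n23_le30 = 46,
      int_ge4_sizes = c(le30 = 0, `30to60` = 19, gt60 = 19),
      int_n23_sizes = c(`30to60` = 10, gt60 = 7),
      adv_sizes = c(le30 = 0, `30to60` = 18, gt60 = 20),
      child_b = c(early = 10, intermediate = 7, advanced = 6),
      marginals = list(
        male = 214, comorbidity_gt1 = 10,
        aetiology = c(alcohol = 113, hcv = 89, hbv = 34, nash = 20, other = 10),
        afp_cat = c(le100 = 189, `100to1000` = 48, gt1000 = 29),
        portal_htn = 154, bilobar = 64
      ),
      medians = c(resection = 35, ablation = 35, tace = 12, sorafenib = 4)
    )
  } else {
    list(
      n = 266,
      stages = c(very_early = 22, early = 146, intermediate = 55, advanced = 43),
      joint = rbind(
        very_early   = c(resection = 0, ablation = 22, tace = 0, sorafenib = 0),
        early        = c(35, 35, 72, 4),
        intermediate = c(0, 5, 50, 0),
        advanced     = c(0, 2, 6, 35)
      ),
      early_n1_sizes = c(le30 = 52, `30to60` = 39, gt60 = 10),
      early_n23_le30 = 45,
      int_ge4_sizes = c(le30 = 0, `30to60` = 22, gt60 = 17),
      int_n23_sizes = c(`30to60` = 9, gt60 = 7),
      adv_sizes = c(le30 = 0, `30to60` = 23, gt60 = 20),
      child_b = c(early = 10, intermediate = 6, advanced = 6),
      marginals = list(
        male = 211, comorbidity_gt1 = 19,
        aetiology = c(alcohol = 117, hcv = 88, hbv = 32, nash = 22, other = 7),
        afp_cat = c(le100 = 178, `100to1000` = 50, gt1000 = 38),
        portal_htn = 146, bilobar = 64
      ),
      medians = c(resection = 55, ablation = 37, tace = 18, sorafenib = 9)
    )
  }
}

.build_fixture_group <- function(group) {
  bp <- .fixture_blueprint(group)
  n <- bp$n
  stages <- rep(names(bp$stages), bp$stages)

  # tumour structure per stage block, deterministic order inside each block
  n_cat <- character(n); mm_cat <- character(n); mm <- numeric(n)
  fill <- function(idx, ncat, scat) {
    n_cat[idx] <<- ncat; mm_cat[idx] <<- scat
    mm[idx] <<- switch(scat, le30 = 25, `30to60` = 45, gt60 = 70)
  }
  i_ve <- which(stages == "very_early")
  n_cat[i_ve] <- "1"; mm_cat[i_ve] <- "le30"; mm[i_ve] <- 18
  i_e <- which(stages == "early")
  p <- i_e[1] - 1
  for (s in names(bp$early_n1_sizes)) {
    k <- bp$early_n1_sizes[[s]]
    if (k > 0) { fill(p + seq_len(k), "1", s); p <- p + k }
  }
  if (bp$early_n23_le30 > 0) { fill(p + seq_len(bp$early_n23_le30), "2_3", "le30"); p <- p + bp$early_n23_le30 }
  stopifnot(p == i_e[length(i_e)])
  i_i <- which(stages == "intermediate")
  p <- i_i[1] - 1
  for (s in names(bp$int_ge4_sizes)) {
    k <- bp$int_ge4_sizes[[s]]
    if (k > 0) { fill(p + seq_len(k), "ge4", s); p <- p + k }
  }
  for (s in names(bp$int_n23_sizes)) {
    k <- bp$int_n23_sizes[[s]]
    if (k > 0) { fill(p + seq_len(k), "2_3", s); p <- p + k }
  }
  stopifnot(p == i_i[length(i_i)])
  i_a <- which(stages == "advanced")
  p <- i_a[1] - 1
  for (s in names(bp$adv_sizes)) {
    k <- bp$adv_sizes[[s]]
    if (k > 0) { fill(p + seq_len(k), "1", s); p <- p + k }
  }
  stopifnot(p == n)

  # first-line arm within each stage block (deterministic interleave)
  arm <- character(n)
  for (st in names(bp$stages)) {
    idx <- which(stages == st)
    arm[idx] <- .assign_categorical(length(idx), bp$joint[st, ])
  }

  # Child-Pugh B assigned within the allowed stage blocks (never very early)
  child <- rep("A", n)
  for (st in names(bp$child_b)) {
    idx <- which(stages == st)
    child[idx[.spread_positions(length(idx), bp$child_b[[st]])]] <- "B"
  }

  # unconstrained covariates by even interleave over the roster
  male    <- seq_len(n) %in% .spread_positions(n, bp$marginals$male)
  comorb  <- seq_len(n) %in% .spread_positions(n, bp$marginals$comorbidity_gt1)
  pht     <- seq_len(n) %in% .spread_positions(n, bp$marginals$portal_htn)
  bilo    <- seq_len(n) %in% .spread_positions(n, bp$marginals$bilobar)
  aetio   <- .assign_categorical(n, bp$marginals$aetiology)
  afp     <- .assign_categorical(n, bp$marginals$afp_cat)

  # age: truncated-normal quantiles visited through a fixed stride permutation
  # (stride 9 is coprime with 266) so age is spread across stage blocks
  perm <- (9 * (seq_len(n) - 1)) %% n + 1
  age <- pmin(pmax(qnorm((perm - 0.5) / n, 66, 11), 18), 95)

  # survival: per-arm exponential quantile grid at the group x arm median,
  # administratively censored at 84 months (synthetic-only follow-up)
  time_months <- numeric(n); event <- logical(n)
  for (a in .levels$first_line) {
    idx <- which(arm == a)
    if (!length(idx)) next
    r <- log(2) / bp$medians[[a]]
    tt <- qexp((seq_along(idx) - 0.5) / length(idx), rate = r)
    event[idx] <- tt < 84
    time_months[idx] <- pmin(tt, 84)
  }

  data.frame(
    id = sprintf("%s-%04d", group, seq_len(n)),
    group = factor(group, .levels$group),
    age = age, male = male, comorbidity_gt1 = comorb,
    aetiology = factor(aetio, .levels$aetiology),
    child_pugh = factor(child, .levels$child_pugh),
    portal_htn = pht,
    afp_cat = factor(afp, .levels$afp_cat),
    n_tumors_cat = factor(n_cat, .levels$n_tumors_cat),
    largest_mm = mm,
    largest_mm_cat = factor(mm_cat, .levels$largest_mm_cat),
    bilobar = bilo,
    vascular_invasion = stages == "advanced",
    performance_status = 0L,
    first_line = factor(arm, .levels$first_line),
    time_months = time_months, event = event,
    stringsAsFactors = FALSE
  )[, .patient_cols]
}

.fixture_check <- function(df, group) {
  bp <- .fixture_blueprint(group)
  fail <- function(what) stop("fixture-integrity error: ", what, call. = FALSE)
  if (nrow(df) != bp$n) fail("cohort size")
  st <- .stage_vec(df)
  if (!identical(as.integer(table(factor(st, .levels$stage))),
                 as.integer(bp$stages))) fail("stage totals")
  jt <- table(factor(st, .levels$stage), df$first_line)
  if (!identical(matrix(as.integer(jt), 4, 4),
                 matrix(as.integer(bp$joint), 4, 4))) fail("stage x arm joint counts")
  m <- bp$marginals
  if (sum(df$male) != m$male) fail("male count")
  if (sum(df$comorbidity_gt1) != m$comorbidity_gt1) fail("comorbidity count")
  if (sum(df$portal_htn) != m$portal_htn) fail("portal hypertension count")
  if (sum(df$bilobar) != m$bilobar) fail("bilobar count")
  if (!identical(as.vector(table(df$aetiology)), as.integer(m$aetiology))) fail("aetiology counts")
  if (!identical(as.vector(table(df$afp_cat)), as.integer(m$afp_cat))) fail("AFP counts")
  # structural marginals implied by the blueprint
  tum <- c(`1` = sum(bp$stages[c("very_early")]) + sum(bp$early_n1_sizes) + bp$stages[["advanced"]],
           `2_3` = bp$early_n23_le30 + sum(bp$int_n23_sizes),
           ge4 = sum(bp$int_ge4_sizes))
  if (!identical(as.integer(table(df$n_tumors_cat)), as.integer(tum))) fail("tumour-number counts")
  siz <- c(le30 = bp$stages[["very_early"]] + bp$early_n1_sizes[["le30"]] + bp$early_n23_le30,
           `30to60` = bp$early_n1_sizes[["30to60"]] + bp$int_ge4_sizes[["30to60"]] +
             bp$int_n23_sizes[["30to60"]] + bp$adv_sizes[["30to60"]],
           gt60 = bp$early_n1_sizes[["gt60"]] + bp$int_ge4_sizes[["gt60"]] +
             bp$int_n23_sizes[["gt60"]] + bp$adv_sizes[["gt60"]])
  if (!identical(as.integer(table(df$largest_mm_cat)), as.integer(siz))) fail("tumour-size counts")
  if (sum(df$child_pugh == "B") != sum(bp$child_b)) fail("Child-Pugh counts")
  if (sum(df$vascular_invasion) != bp$stages[["advanced"]]) fail("vascular invasion count")
  if (any(df$event & df$time_months <= 0) || any(df$time_months < 0)) fail("survival outcome invariants")
  invisible(TRUE)
}

#' Deterministic matched-cohort fixture
#'
#' Returns the two matched 266-patient cohorts (extended-ablation centre
#' "bondy" and standard-of-care "soc") whose covariate category counts equal
#' the matched-column case mix and whose stage-by-first-line joint counts
#' equal the published allocation (bondy: 1 resection, 188 ablations of which
#' 21 intermediate and 11 advanced, 47 TACE, 30 sorafenib; soc: 35 / 64 /
#' 128 / 39). The construction is pure (no randomness) and its internal
#' consistency is asserted cell by cell at build time.
#'
#' Survival times are a deterministic exponential quantile grid at each
#' (group, arm) median, censored at 84 months; they are synthetic-only.
#'
#' @return a list with elements `bondy` and `soc`, each a patient data frame.
#' @export
matched_fixture <- function() {
  bondy <- .build_fixture_group("bondy")
  soc <- .build_fixture_group("soc")
  .fixture_check(bondy, "bondy")
  .fixture_check(soc, "soc")
  list(bondy = bondy, soc = soc)
}

#' Inject missing values into a cohort
#'
#' Masks each maskable covariate independently with its per-covariate rate.
#' Outcome fields (`time_months`, `event`) and structural fields are never
#' masked. Same `(cohort, rates, seed)` gives an identical missingness
#' pattern.
#'
#' @param cohort patient data frame.
#' @param rates named vector of probabilities in `[0, 1]`; names must be
#'   maskable covariates (any of the eleven matching covariates).
#' @param seed integer seed.
#' @return the cohort with `NA`s inserted.
#' @export
inject_missingness <- function(cohort, rates, seed) {
  if (any(rates < 0) || any(rates > 1)) {
    stop("configuration error: missingness rates must lie in [0, 1]", call. = FALSE)
  }
  bad <- setdiff(names(rates), .matching_covariates)
  if (length(bad)) {
    stop("configuration error: not maskable covariates: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  withr::with_seed(seed, {
    for (f in names(rates)) {
      if (rates[[f]] == 0) next
      mask <- runif(nrow(cohort)) < rates[[f]]
      cohort[[f]][mask] <- NA
    }
  })
  cohort
}

#' Read and write cohort CSV files
#'
#' One header row; columns exactly the patient fields in declared order;
#' booleans as 0/1; missing values as empty strings; months as decimals.
#'
#' @param cohort patient data frame.
#' @param path file path.
#' @return `read_cohort_csv` returns a patient data frame;
#'   `write_cohort_csv` returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- cohort[, .patient_cols]
  for (f in names(out)) {
    if (is.logical(out[[f]])) out[[f]] <- as.integer(out[[f]])
  }
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(id = "character"), na.strings = "")
  if (!identical(names(df), .patient_cols)) {
    stop("cohort CSV columns do not match the declared patient layout", call. = FALSE)
  }
  for (f in c("male", "comorbidity_gt1", "portal_htn", "bilobar",
              "vascular_invasion", "event")) {
    df[[f]] <- as.logical(df[[f]])
  }
  df$group <- factor(df$group, .levels$group)
  df$aetiology <- factor(df$aetiology, .levels$aetiology)
  df$child_pugh <- factor(df$child_pugh, .levels$child_pugh)
  df$afp_cat <- factor(df$afp_cat, .levels$afp_cat)
  df$n_tumors_cat <- factor(df$n_tumors_cat, .levels$n_tumors_cat)
  df$largest_mm_cat <- factor(df$largest_mm_cat, .levels$largest_mm_cat)
  df$first_line <- factor(df$first_line, .levels$first_line)
  df
}
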