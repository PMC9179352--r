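# Configuration files, report assembly and run metadata (seed / config hash)
# shared by the command-line interface under inst/cli.

#' Read and write model configuration files
#'
#' The configuration is a YAML (or JSON) document with the cost schedule,
#' discount specification, first-line weights and per-(group, arm)
#' calibration targets, defaulting to [base_case_config()].
#'
#' @param config a configuration list as produced by [base_case_config()].
#' @param path file path; format chosen by extension (`.json` or
#'   `.yaml`/`.yml`).
#' @return `read_model_config` returns a configuration list usable by
#'   [calibrate_base_model()].
#' @export
write_model_config <- function(config, path) {
  ser <- list(
    costs = unclass(config$costs),
    discount = unclass(config$discount)[c("annual_rate", "cycle_months", "horizon_years")],
    weights = lapply(config$weights, as.list),
    targets = lapply(config$targets, function(df) {
      stats::setNames(lapply(seq_len(nrow(df)), function(i)
        list(life_years = df$life_years[i], cost = df$cost[i])), df$arm)
    })
  )
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(ser, path, precision = 15)
  }
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  costs <- do.call(cost_schedule, as.list(raw$costs))
  discount <- do.call(discount_spec, as.list(raw$discount))
  weights <- lapply(raw$weights, function(w) unlist(w))
  targets <- lapply(raw$targets, function(tl) {
    if (is.data.frame(tl)) return(tl)
    data.frame(arm = names(tl),
               life_years = vapply(tl, function(x) x$life_years, numeric(1)),
               cost = vapply(tl, function(x) x$cost, numeric(1)))
  })
  list(costs = costs, discount = discount, weights = weights, targets = targets)
}

#' Read and write cohort-profile files
#'
#' Serialises a [cohort_profile()] to YAML (or JSON). Default files
#' reproducing the shipped case mix are installed under
#' `system.file("extdata", package = "ablateCEA")`.
#'
#' @param profile a [cohort_profile()].
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return `read_cohort_profile` returns a [cohort_profile()].
#' @export
write_cohort_profile <- function(profile, path) {
  ser <- list(
    n = profile$n, group = profile$group,
    covariate_marginals = lapply(profile$covariate_marginals, as.list),
    stage_distribution = as.list(profile$stage_distribution),
    allocation_policy = stats::setNames(
      lapply(rownames(profile$allocation_policy), function(s) {
        as.list(profile$allocation_policy[s, ])
      }), rownames(profile$allocation_policy)),
    survival_medians = as.list(profile$survival_medians),
    censor_horizon_months = profile$censor_horizon_months,
    missing_rate = if (is.null(profile$missing_rate)) NULL else as.list(profile$missing_rate),
    age_mean = profile$age_mean, age_sd = profile$age_sd
  )
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(ser, path, precision = 15)
  }
  invisible(path)
}

#' @rdname write_cohort_profile
#' @export
read_cohort_profile <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  pol <- do.call(rbind, lapply(raw$allocation_policy, unlist))
  cohort_profile(
    n = raw$n, group = raw$group,
    covariate_marginals = lapply(raw$covariate_marginals, unlist),
    stage_distribution = unlist(raw$stage_distribution),
    allocation_policy = pol,
    survival_medians = unlist(raw$survival_medians),
    censor_horizon_months = raw$censor_horizon_months,
    missing_rate = if (is.null(raw$missing_rate)) NULL else unlist(raw$missing_rate),
    age_mean = raw$age_mean, age_sd = raw$age_sd
  )
}

# stable short hash of a configuration list, embedded in outputs for audit
config_hash <- function(config) {
  txt <- paste(utils::capture.output(utils::str(config, digits.d = 12)), collapse = "\n")
  # small rolling hash (no digest dependency); stable across sessions
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Assemble the final cost-effectiveness report
#'
#' Produces the per-arm table of weighted cost and life-year contributions,
#' net effects, group totals and the ICER/dominance classification, in euros
#' with dollars at the fixed conversion factor.
#'
#' @param cea a [run_weighted_cea()] result.
#' @param usd_per_eur conversion factor.
#' @return list with `per_arm` (data frame: arm, bondy/soc cost and
#'   life-year contributions, net effects, dollar columns), `totals`, `ce`.
#' @export
cea_report <- function(cea, usd_per_eur = 1.10) {
  cb <- cea$totals$bondy$contributions
  cs <- cea$totals$soc$contributions
  per_arm <- data.frame(
    arm = cb$arm,
    bondy_cost_eur = cb$cost, soc_cost_eur = cs$cost,
    net_cost_eur = cb$cost - cs$cost,
    bondy_life_years = cb$life_years, soc_life_years = cs$life_years,
    net_life_years = cb$life_years - cs$life_years
  )
  per_arm$bondy_cost_usd <- to_usd(per_arm$bondy_cost_eur, usd_per_eur)
  per_arm$soc_cost_usd <- to_usd(per_arm$soc_cost_eur, usd_per_eur)
  per_arm$net_cost_usd <- to_usd(per_arm$net_cost_eur, usd_per_eur)
  totals <- data.frame(
    group = c("bondy", "soc"),
    cost_eur = c(cea$totals$bondy$total_cost, cea$totals$soc$total_cost),
    life_years = c(cea$totals$bondy$total_life_years,
                   cea$totals$soc$total_life_years)
  )
  totals$cost_usd <- to_usd(totals$cost_eur, usd_per_eur)
  list(per_arm = per_arm, totals = totals, ce = cea$ce)
}

#' Write a JSON result summary with run metadata
#'
#' Every output embeds the seed and a configuration hash so stochastic
#' stages are auditable.
#'
#' @param x a serialisable list.
#' @param path output path.
#' @param seed the seed used by the run (or `NA`).
#' @param config the configuration the run used (hashed into the output).
#' @return invisibly `path`.
#' @export
write_result_json <- function(x, path, seed = NA, config = NULL) {
  meta <- list(seed = seed,
               config_hash = if (is.null(config)) NA else config_hash(config))
  jsonlite::write_json(c(list(meta = meta), x), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
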