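# One-way deterministic sensitivity analysis and probabilistic sensitivity
# analysis (Monte Carlo) on the cost-effectiveness plane.

#' Uncertain-parameter specification
#'
#' One parameter's sampling distribution for DSA/PSA, described by its
#' distribution family and (mode, min, max) bounds. Cost parameters use
#' gamma, start age and the discount rate triangular, transition
#' probabilities beta on bounds 10% below/above the base value; lognormal is
#' available as an option. The distribution spread rule (standard deviation
#' `(max - min) / 4`, values truncated to `[min, max]`) is fixed here and
#' documented in the methods vignette.
#'
#' @param name parameter id.
#' @param family `"gamma"`, `"beta"`, `"triangular"` or `"lognormal"`.
#' @param mode base value.
#' @param min,max lower/upper bounds; `min <= mode <= max` required.
#' @param target where the parameter applies in the model set: a list with
#'   `type` in `"cost"`, `"transition"`, `"discount"`, `"start_age"` and, as
#'   needed, `field`, `group`, `arm`.
#' @return an object of class `param_spec`.
#' @export
param_spec <- function(name, family = c("gamma", "beta", "triangular", "lognormal"),
                       mode, min, max, target = list(type = "none")) {
  family <- match.arg(family)
  if (min > max) stop("configuration error: min > max for parameter ", name, call. = FALSE)
  if (mode < min || mode > max) {
    stop("configuration error: mode outside [min, max] for parameter ", name, call. = FALSE)
  }
  structure(list(name = name, family = family, mode = mode, min = min,
                 max = max, target = target), class = "param_spec")
}

.rtriangular <- function(n, a, c, b) {
  u <- runif(n)
  fc <- (c - a) / (b - a)
  ifelse(u < fc, a + sqrt(u * (b - a) * (c - a)),
         b - sqrt((1 - u) * (b - a) * (b - c)))
}

.reject_trunc <- function(draw, lo, hi, n) {
  out <- numeric(0)
  for (i in 1:1000) {
    need <- n - length(out)
    if (need <= 0) break
    x <- draw(max(need * 2, 16))
    out <- c(out, x[x >= lo & x <= hi])
  }
  if (length(out) < n) stop("truncation rejection failed to produce draws in bounds", call. = FALSE)
  out[seq_len(n)]
}

#' Sample values from a parameter specification
#'
#' Gamma: shape/scale chosen so the mode equals `mode` and the standard
#' deviation equals `(max - min) / 4`, rejection-truncated to the bounds.
#' Triangular: standard triangular(min, mode, max). Beta: scaled to
#' `[min, max]` with the mode at `mode` and concentration giving the same
#' standard-deviation rule. Lognormal: mode-matched with that standard
#' deviation, truncated. A degenerate spec (min = mode = max) returns the
#' mode.
#'
#' @param spec a [param_spec()].
#' @param n number of draws.
#' @return numeric vector of length `n`, all within `[min, max]`.
#' @export
sample_param <- function(spec, n = 1) {
  m <- spec$mode; lo <- spec$min; hi <- spec$max
  if (lo == hi) return(rep(m, n))
  s <- (hi - lo) / 4
  switch(spec$family,
    triangular = .rtriangular(n, lo, m, hi),
    gamma = {
      if (m <= 0) stop("gamma parameter requires a positive mode", call. = FALSE)
      u <- (m / s + sqrt((m / s)^2 + 4)) / 2
      shape <- u^2
      scale <- s / u
      .reject_trunc(function(k) rgamma(k, shape = shape, scale = scale), lo, hi, n)
    },
    beta = {
      cc <- (m - lo) / (hi - lo)
      target_var <- (1 / 4)^2
      vfun <- function(nu) {
        a <- cc * (nu - 2) + 1; b <- (1 - cc) * (nu - 2) + 1
        a * b / ((a + b)^2 * (a + b + 1)) - target_var
      }
      nu <- tryCatch(uniroot(vfun, c(2 + 1e-9, 1e7))$root,
                     error = function(e) 4)
      a <- cc * (nu - 2) + 1; b <- (1 - cc) * (nu - 2) + 1
      lo + (hi - lo) * rbeta(n, a, b)
    },
    lognormal = {
      if (m <= 0) stop("lognormal parameter requires a positive mode", call. = FALSE)
      g <- function(s2) m^2 * (exp(s2) - 1) * exp(3 * s2) - s^2
      s2 <- uniroot(g, c(1e-12, 50))$root
      mu <- log(m) + s2
      .reject_trunc(function(k) rlnorm(k, meanlog = mu, sdlog = sqrt(s2)), lo, hi, n)
    }
  )
}

#' Default uncertain-parameter set
#'
#' The shipped DSA/PSA parameter list: the eight cost items (gamma, printed
#' mode/min/max bounds), start age (triangular 65, 60--67; the calibrated
#' model carries no age-specific background mortality, so this parameter has
#' no output leverage and is retained for completeness), the discount rate
#' (triangular 3%, 0--6%) and, per (group, arm), the calibrated death and
#' retreatment probabilities (beta, bounds 10% below/above the calibrated
#' value).
#'
#' @param model_set a [calibrate_base_model()] result supplying the
#'   calibrated transition modes.
#' @return list of [param_spec()] objects.
#' @export
default_param_specs <- function(model_set) {
  cost_bounds <- list(
    resection = c(17666, 16900, 18300),
    ablation = c(4895, 4400, 5000),
    tace = c(5708, 5500, 5800),
    sorafenib_cycle = c(4500, 2935, 10320),
    transplant = c(51779, 48900, 54000),
    followup_post_curative_cycle = c(146, 100, 500),
    followup_post_tace_cycle = c(379, 100, 800),
    followup_post_transplant_cycle = c(1514, 594, 2000)
  )
  specs <- list()
  for (f in names(cost_bounds)) {
    b <- cost_bounds[[f]]
    specs[[paste0("cost_", f)]] <- param_spec(
      paste0("cost_", f), "gamma", b[1], b[2], b[3],
      target = list(type = "cost", field = f))
  }
  specs$start_age <- param_spec("start_age", "triangular", 65, 60, 67,
                                target = list(type = "start_age"))
  specs$discount_rate <- param_spec("discount_rate", "triangular", 0.03, 0, 0.06,
                                    target = list(type = "discount"))
  for (g in c("bondy", "soc")) {
    for (a in names(model_set$params[[g]])) {
      p <- model_set$params[[g]][[a]]
      for (f in c("p_death", "p_retreat")) {
        v <- p[[f]]
        specs[[paste(f, g, a, sep = "_")]] <- param_spec(
          paste(f, g, a, sep = "_"), "beta", v, 0.9 * v, 1.1 * v,
          target = list(type = "transition", group = g, arm = a, field = f))
      }
    }
  }
  specs
}

# Apply a named vector of sampled values to a model set copy.
apply_param_values <- function(model_set, specs, values) {
  for (nm in names(values)) {
    tg <- specs[[nm]]$target
    v <- values[[nm]]
    if (tg$type == "cost") {
      model_set$costs[[tg$field]] <- v
    } else if (tg$type == "transition") {
      model_set$params[[tg$group]][[tg$arm]][[tg$field]] <- v
    } else if (tg$type == "discount") {
      model_set$discount$annual_rate <- v
    }
    # start_age: recorded but has no leverage in this model structure
  }
  model_set
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the full weighted cost-effectiveness analysis with each parameter
#' at its minimum and at its maximum, all others at their mode, and sorts
#' the entries by output range (tornado order; the range of each increment
#' is normalised by the base-case increment magnitude and the larger of the
#' cost/effect relative ranges is the sort key). A model failure at an
#' extreme flags the entry and the analysis continues.
#'
#' @param model_set a [calibrate_base_model()] result.
#' @param specs list of [param_spec()] (default: [default_param_specs()]).
#' @return data frame with one row per parameter: increments at min and max,
#'   ranges, failure flag, sorted widest first.
#' @export
one_way_dsa <- function(model_set, specs = default_param_specs(model_set)) {
  base <- run_weighted_cea(model_set)$ce
  eval_at <- function(spec, value) {
    tryCatch({
      ms <- apply_param_values(model_set, specs,
                               structure(list(value), names = spec$name))
      ce <- run_weighted_cea(ms)$ce
      c(cost = ce$incremental_cost, effect = ce$incremental_effect, failed = 0)
    }, error = function(e) c(cost = NA_real_, effect = NA_real_, failed = 1))
  }
  rows <- lapply(specs, function(sp) {
    at_min <- eval_at(sp, sp$min)
    at_max <- eval_at(sp, sp$max)
    data.frame(
      parameter = sp$name,
      cost_at_min = at_min[["cost"]], cost_at_max = at_max[["cost"]],
      effect_at_min = at_min[["effect"]], effect_at_max = at_max[["effect"]],
      failed = (at_min[["failed"]] + at_max[["failed"]]) > 0
    )
  })
  out <- do.call(rbind, rows)
  out$cost_range <- abs(out$cost_at_max - out$cost_at_min)
  out$effect_range <- abs(out$effect_at_max - out$effect_at_min)
  sc <- max(abs(base$incremental_cost), 1e-9)
  se <- max(abs(base$incremental_effect), 1e-9)
  out$rel_range <- pmax(out$cost_range / sc, out$effect_range / se)
  out <- out[order(-out$rel_range), ]
  rownames(out) <- NULL
  out
}

#' Quadrant fractions of a cost-effectiveness plane
#'
#' Classifies incremental points by the signs of (effect, cost) with the
#' comparator at the origin. The lower-right quadrant (more effective,
#' cheaper) is dominant; points exactly on an axis are assigned to the
#' adjacent non-dominant quadrant (conservative convention).
#'
#' @param points data frame with `incremental_effect` and
#'   `incremental_cost`.
#' @return named numeric vector of four fractions (`ne`, `se_dominant`,
#'   `sw`, `nw_dominated`) summing to 1.
#' @export
quadrant_fractions <- function(points) {
  if (nrow(points) == 0) stop("empty point set", call. = FALSE)
  de <- points$incremental_effect; dc <- points$incremental_cost
  dominant <- de > 0 & dc < 0
  ne <- de >= 0 & dc >= 0
  nw <- de < 0 & dc >= 0
  sw <- de <= 0 & dc < 0
  n <- nrow(points)
  c(ne = sum(ne) / n, se_dominant = sum(dominant) / n,
    sw = sum(sw) / n, nw_dominated = sum(nw) / n)
}

#' Probabilistic sensitivity analysis
#'
#' Each draw samples every uncertain parameter independently from its
#' specification, re-runs the weighted cost-effectiveness analysis for both
#' groups and records the incremental point. Draws producing an invalid
#' model (e.g. transition rows exceeding 1) are rejected and redrawn, with
#' the rejection count reported. Fully reproducible from the seed.
#'
#' @param model_set a [calibrate_base_model()] result.
#' @param specs list of [param_spec()] (default: [default_param_specs()]).
#' @param n_draws number of Monte Carlo draws (default 1000).
#' @param seed integer seed.
#' @return an object of class `psa_result`: `points` (data frame draw,
#'   incremental_cost, incremental_effect), `n_draws`, `n_rejected`,
#'   `quadrant_fractions`, `dominant_fraction`, `mean_incremental_cost`,
#'   `mean_incremental_effect`, `ci_cost`, `ci_effect` (2.5/97.5
#'   percentiles), `seed`.
#' @export
run_psa <- function(model_set, specs = default_param_specs(model_set),
                    n_draws = 1000, seed = 1) {
  withr::with_seed(seed, {
    dc <- numeric(n_draws); de <- numeric(n_draws)
    n_rejected <- 0L
    for (i in seq_len(n_draws)) {
      repeat {
        values <- lapply(specs, function(sp) sample_param(sp, 1))
        names(values) <- vapply(specs, `[[`, character(1), "name")
        res <- tryCatch({
          ms <- apply_param_values(model_set, specs, values)
          run_weighted_cea(ms)$ce
        }, error = function(e) NULL)
        if (!is.null(res)) break
        n_rejected <- n_rejected + 1L
        if (n_rejected > 100 * n_draws) {
          stop("PSA rejection rate implausibly high; check parameter bounds", call. = FALSE)
        }
      }
      dc[i] <- res$incremental_cost
      de[i] <- res$incremental_effect
    }
  })
  points <- data.frame(draw = seq_len(n_draws),
                       incremental_cost = dc, incremental_effect = de)
  qf <- quadrant_fractions(points)
  structure(list(
    points = points, n_draws = n_draws, n_rejected = n_rejected,
    quadrant_fractions = qf,
    dominant_fraction = qf[["se_dominant"]],
    mean_incremental_cost = mean(dc),
    mean_incremental_effect = mean(de),
    ci_cost = unname(quantile(dc, c(0.025, 0.975))),
    ci_effect = unname(quantile(de, c(0.025, 0.975))),
    seed = seed
  ), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d draws (seed %d, %d rejected)\n", x$n_draws, x$seed, x$n_rejected))
  cat(sprintf("  mean increment: %.0f EUR, %.2f LYG\n",
              x$mean_incremental_cost, x$mean_incremental_effect))
  cat(sprintf("  95%% CI cost: [%.0f, %.0f] EUR; effect: [%.2f, %.2f] LYG\n",
              x$ci_cost[1], x$ci_cost[2], x$ci_effect[1], x$ci_effect[2]))
  cat(sprintf("  dominant fraction (lower-right quadrant): %.3f\n", x$dominant_fraction))
  invisible(x)
}

#' Export sensitivity-analysis artefacts
#'
#' PSA points as CSV (draw, incremental_cost_eur, incremental_effect_lyg),
#' summary as JSON (quadrant fractions, means, CIs, seed, draws), tornado
#' table as CSV.
#'
#' @param psa a [run_psa()] result.
#' @param dsa a [one_way_dsa()] result.
#' @param points_path,summary_path,tornado_path output paths.
#' @return invisibly `NULL`.
#' @export
export_sensitivity <- function(psa = NULL, dsa = NULL, points_path = NULL,
                               summary_path = NULL, tornado_path = NULL) {
  if (!is.null(psa) && !is.null(points_path)) {
    pts <- psa$points
    names(pts) <- c("draw", "incremental_cost_eur", "incremental_effect_lyg")
    write.csv(pts, points_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(psa) && !is.null(summary_path)) {
    jsonlite::write_json(list(
      n_draws = psa$n_draws, n_rejected = psa$n_rejected, seed = psa$seed,
      quadrant_fractions = as.list(psa$quadrant_fractions),
      dominant_fraction = psa$dominant_fraction,
      mean_incremental_cost = psa$mean_incremental_cost,
      mean_incremental_effect = psa$mean_incremental_effect,
      ci_cost = psa$ci_cost, ci_effect = psa$ci_effect
    ), summary_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(dsa) && !is.null(tornado_path)) {
    write.csv(dsa, tornado_path, row.names = FALSE, quote = FALSE)
  }
  invisible(NULL)
}
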