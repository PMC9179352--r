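# Kaplan-Meier estimation, log-rank comparison, parametric fitting with BIC
# selection, and median/rate/cycle-probability conversions.
#
# The product-limit estimator and the log-rank statistic are computed by the
# survival package (survfit / survdiff); parametric Weibull and Gompertz fits
# by flexsurv; the exponential fit has a closed form (events / total time).

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator with ties handled by simultaneous decrement.
#' The median is the smallest time with S(t) <= 0.5 (undefined, `NA`, if the
#' curve never reaches 0.5); the IQR bounds are defined analogously at
#' S <= 0.75 and S <= 0.25.
#'
#' @param times non-negative follow-up times (months).
#' @param events logical/0-1 event indicators (TRUE = death observed).
#' @return an object of class `km_curve`: list with `times`, `survival`,
#'   `n_risk`, `n_event`, `median`, `iqr` (q1, q3) and the underlying
#'   `survfit` object.
#' @export
km_fit <- function(times, events) {
  if (length(times) == 0) stop("empty input: no survival times", call. = FALSE)
  stopifnot(length(times) == length(events), all(times >= 0))
  events <- as.logical(events)
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  qtl <- function(p) {
    i <- which(sf$surv <= p)
    if (length(i)) sf$time[min(i)] else NA_real_
  }
  structure(list(
    times = sf$time, survival = sf$surv,
    n_risk = sf$n.risk, n_event = sf$n.event,
    median = qtl(0.5), iqr = c(q1 = qtl(0.75), q3 = qtl(0.25)),
    n = length(times), survfit = sf
  ), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, median = %s months (IQR %s-%s)\n",
              x$n, sum(x$n_event),
              format(x$median), format(x$iqr[[1]]), format(x$iqr[[2]])))
  invisible(x)
}

#' Two-sample log-rank test
#'
#' @param times_a,events_a follow-up and event indicators for group A.
#' @param times_b,events_b same for group B.
#' @return list with `statistic` (chi-square, 1 df) and `p_value`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0 || length(times_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (sum(events_a) + sum(events_b) == 0) {
    stop("log-rank test undefined without any events", call. = FALSE)
  }
  time <- c(times_a, times_b)
  status <- as.logical(c(events_a, events_b))
  grp <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(time, status) ~ grp)
  list(statistic = sd$chisq, p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Parametric survival fit with right censoring
#'
#' Maximum-likelihood fit of an exponential, Weibull or Gompertz survival
#' distribution. The exponential rate has the closed form
#' `events / sum(times)`; Weibull and Gompertz are fitted numerically
#' (flexsurv), the Gompertz hazard being `a * exp(b * t)` with shape `b`
#' unrestricted and rate `a > 0`. The BIC uses `k * log(n) - 2 * loglik`
#' with `n` the total number of subjects (events plus censored).
#'
#' @param times non-negative follow-up times (months).
#' @param events event indicators; at least one event required.
#' @param family `"exponential"`, `"weibull"` or `"gompertz"`.
#' @return an object of class `parametric_fit`: list with `family`, `params`,
#'   `loglik`, `bic`, `median_months`, `n`, `n_events`.
#' @export
fit_parametric <- function(times, events,
                           family = c("exponential", "weibull", "gompertz")) {
  family <- match.arg(family)
  events <- as.logical(events)
  stopifnot(length(times) == length(events), all(times >= 0))
  if (sum(events) < 1) stop("at least one event is required", call. = FALSE)
  n <- length(times)
  if (family == "exponential") {
    lambda <- sum(events) / sum(times)
    loglik <- sum(events) * log(lambda) - lambda * sum(times)
    params <- c(rate = lambda)
    median_months <- log(2) / lambda
    k <- 1L
  } else {
    fit <- tryCatch(
      flexsurv::flexsurvreg(survival::Surv(times, events) ~ 1,
                            dist = if (family == "weibull") "weibull" else "gompertz"),
      error = function(e) {
        stop("non-convergence in ", family, " fit: ", conditionMessage(e), call. = FALSE)
      }
    )
    params <- fit$res[, "est"]
    loglik <- fit$loglik
    median_months <- unname(
      if (family == "weibull") {
        qweibull(0.5, shape = params[["shape"]], scale = params[["scale"]])
      } else {
        flexsurv::qgompertz(0.5, shape = params[["shape"]], rate = params[["rate"]])
      }
    )
    k <- 2L
  }
  structure(list(
    family = family, params = params, loglik = loglik,
    bic = k * log(n) - 2 * loglik, k = k,
    median_months = median_months, n = n, n_events = sum(events)
  ), class = "parametric_fit")
}

#' @importFrom stats qweibull
NULL

#' @export
print.parametric_fit <- function(x, ...) {
  cat(sprintf("%s fit: loglik %.2f, BIC %.2f, median %.2f months\n",
              x$family, x$loglik, x$bic, x$median_months))
  invisible(x)
}

#' Select the best parametric fit by BIC
#'
#' Returns the minimum-BIC fit among candidates fitted to the same data.
#' Ties are broken deterministically: fewest parameters first, then
#' alphabetical family name.
#'
#' @param fits list of [fit_parametric()] results on identical data.
#' @return the selected `parametric_fit`.
#' @export
select_by_bic <- function(fits) {
  stopifnot(length(fits) >= 1)
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1) {
    stop("fits were computed on different data (mismatched n)", call. = FALSE)
  }
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  k <- vapply(fits, `[[`, numeric(1), "k")
  fam <- vapply(fits, `[[`, character(1), "family")
  fits[[order(bic, k, fam)[1]]]
}

#' Median/rate/cycle-probability conversions
#'
#' Under the exponential survival assumption, a median overall survival `m`
#' months corresponds to a monthly event rate `log(2) / m`, and a constant
#' rate `r` to a per-cycle event probability `1 - exp(-r * cycle_months)`.
#'
#' @param median_months strictly positive median survival in months.
#' @return `median_to_rate`: the monthly rate.
#' @export
median_to_rate <- function(median_months) {
  if (any(median_months <= 0)) stop("median must be strictly positive", call. = FALSE)
  log(2) / median_months
}

#' @rdname median_to_rate
#' @param rate non-negative event rate per month.
#' @param cycle_months strictly positive cycle length in months.
#' @return `rate_to_cycle_prob`: the per-cycle event probability.
#' @export
rate_to_cycle_prob <- function(rate, cycle_months) {
  stopifnot(all(rate >= 0), all(cycle_months > 0))
  1 - exp(-rate * cycle_months)
}

#' Export survival artefacts
#'
#' Curve CSV: time, n_at_risk, n_events, survival. Fit JSON: family, params,
#' loglik, bic, median.
#'
#' @param curve a [km_fit()] result.
#' @param fit a [fit_parametric()] result.
#' @param curve_path,fit_path output paths.
#' @return invisibly `NULL`.
#' @export
export_survival <- function(curve = NULL, fit = NULL,
                            curve_path = NULL, fit_path = NULL) {
  if (!is.null(curve) && !is.null(curve_path)) {
    write.csv(data.frame(
      time = curve$times, n_at_risk = curve$n_risk,
      n_events = curve$n_event, survival = curve$survival
    ), curve_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(fit) && !is.null(fit_path)) {
    jsonlite::write_json(list(
      family = fit$family, params = as.list(fit$params),
      loglik = fit$loglik, bic = fit$bic, median_months = fit$median_months
    ), fit_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(NULL)
}
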