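# Propensity-score estimation, optimal 1:1 matching, multiple imputation and
# covariate balance diagnostics.

.logit <- function(p) log(p / (1 - p))

#' Estimate propensity scores
#'
#' Fits a main-effects logistic regression of group membership (extended
#' ablation centre vs standard of care) on the matching covariates by maximum
#' likelihood. Categorical covariates are one-hot encoded with the first
#' level as reference. Missing values must be imputed first.
#'
#' @param cohort patient data frame containing both groups.
#' @param covariates covariate names (default: the eleven matching
#'   covariates: age, gender, comorbidity index, cirrhosis aetiology,
#'   Child-Pugh class, portal hypertension, AFP level, vascular invasion,
#'   tumour number, largest-tumour size, bilobar involvement).
#' @return an object of class `propensity_model`: list with `scores` (named
#'   by patient id, in (0,1)), `coefficients`, `intercept`, `covariate_list`
#'   and the fitted `model`.
#' @export
estimate_propensity <- function(cohort, covariates = .matching_covariates) {
  if (length(unique(cohort$group)) < 2) {
    stop("degenerate input: both groups must be present to fit a propensity model", call. = FALSE)
  }
  dat <- cohort[, c("group", covariates)]
  if (any(!complete.cases(dat))) {
    stop("missing covariate values: run impute_missing() before estimating propensity scores", call. = FALSE)
  }
  dat$.treated <- as.integer(cohort$group == "bondy")
  f <- stats::as.formula(paste(".treated ~", paste(covariates, collapse = " + ")))
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(f, data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (sep) {
    stop("perfect separation in the propensity model; report exact category composition instead of matching on fitted scores", call. = FALSE)
  }
  cf <- coef(fit)
  if (any(is.na(cf))) {
    stop("singular design in the propensity model; collinear columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  scores <- fit$fitted.values
  names(scores) <- cohort$id
  structure(list(
    scores = scores,
    coefficients = cf[-1],
    intercept = cf[[1]],
    covariate_list = covariates,
    model = fit
  ), class = "propensity_model")
}

#' Optimal 1:1 propensity matching without replacement
#'
#' Pairs treated with control units minimising the total absolute distance
#' between propensity scores on the logit scale over all one-to-one
#' assignments without replacement (a global optimum via a minimum-cost
#' rectangular assignment, not a greedy pass). Pairs whose distance exceeds
#' the caliper are dropped after optimisation. Ties are broken
#' deterministically by (treated id, control id) lexical order.
#'
#' @param treated_scores,control_scores named numeric vectors of propensity
#'   scores in (0,1); names are patient ids.
#' @param caliper optional maximum allowed |logit difference|; `NULL`
#'   (default) disables it.
#' @return an object of class `matched_pairs`: list with `pairs` (data frame
#'   treated_id, control_id, distance), `total_distance`,
#'   `unmatched_treated`, `caliper`.
#' @export
match_optimal <- function(treated_scores, control_scores, caliper = NULL) {
  empty <- function(unmatched) {
    structure(list(
      pairs = data.frame(treated_id = character(0), control_id = character(0),
                         distance = numeric(0), stringsAsFactors = FALSE),
      total_distance = 0, unmatched_treated = unmatched, caliper = caliper
    ), class = "matched_pairs")
  }
  if (length(treated_scores) == 0 || length(control_scores) == 0) {
    warning("empty treated or control side: returning an empty pairing")
    return(empty(names(treated_scores)))
  }
  stopifnot(all(treated_scores > 0 & treated_scores < 1),
            all(control_scores > 0 & control_scores < 1))
  # lexical pre-ordering makes the assignment's tie-breaking deterministic
  treated_scores <- treated_scores[order(names(treated_scores))]
  control_scores <- control_scores[order(names(control_scores))]
  lt <- .logit(treated_scores); lc <- .logit(control_scores)
  cost <- abs(outer(lt, lc, "-"))
  transposed <- length(lt) > length(lc)
  assign <- if (transposed) lsap_solve(t(cost)) else lsap_solve(cost)
  if (transposed) {
    pairs <- data.frame(
      treated_id = names(lt)[assign], control_id = names(lc),
      distance = cost[cbind(assign, seq_along(lc))],
      stringsAsFactors = FALSE
    )
  } else {
    pairs <- data.frame(
      treated_id = names(lt), control_id = names(lc)[assign],
      distance = cost[cbind(seq_along(lt), assign)],
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(caliper)) pairs <- pairs[pairs$distance <= caliper, , drop = FALSE]
  pairs <- pairs[order(pairs$treated_id, pairs$control_id), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(
    pairs = pairs,
    total_distance = sum(pairs$distance),
    unmatched_treated = setdiff(names(lt), pairs$treated_id),
    caliper = caliper
  ), class = "matched_pairs")
}

#' @export
print.matched_pairs <- function(x, ...) {
  cat(sprintf("matched pairs: %d (total logit distance %.4f, %d treated unmatched)\n",
              nrow(x$pairs), x$total_distance, length(x$unmatched_treated)))
  invisible(x)
}

#' Multiple imputation of missing covariates
#'
#' Produces `m` completed copies of the cohort. Each missing categorical (or
#' logical) value is drawn from the observed within-group category
#' frequencies; missing ages are drawn from the observed within-group ages.
#' Imputations are independent given the seed; a covariate observed for no
#' patient at all is an error.
#'
#' @param cohort patient data frame (possibly with `NA` covariates).
#' @param m number of imputations (>= 1).
#' @param seed integer seed.
#' @return list of `m` completed cohorts.
#' @export
impute_missing <- function(cohort, m, seed) {
  stopifnot(m >= 1)
  incomplete <- .matching_covariates[vapply(.matching_covariates,
    function(f) anyNA(cohort[[f]]), logical(1))]
  for (f in incomplete) {
    if (all(is.na(cohort[[f]]))) {
      stop("covariate '", f, "' is missing for all patients; cannot impute", call. = FALSE)
    }
  }
  if (length(incomplete) == 0) return(replicate(m, cohort, simplify = FALSE))
  withr::with_seed(seed, {
    lapply(seq_len(m), function(k) {
      done <- cohort
      for (f in incomplete) {
        for (g in levels(cohort$group)) {
          idx <- which(is.na(done[[f]]) & done$group == g)
          if (!length(idx)) next
          obs <- cohort[[f]][cohort$group == g & !is.na(cohort[[f]])]
          if (!length(obs)) obs <- cohort[[f]][!is.na(cohort[[f]])]
          done[[f]][idx] <- sample(obs, length(idx), replace = TRUE)
        }
      }
      done
    })
  })
}

.smd_one <- function(x_t, x_c, x_pre_t, x_pre_c) {
  # pooled pre-match SD as the normaliser for both pre and post SMDs
  s <- sqrt((stats::var(as.numeric(x_pre_t)) + stats::var(as.numeric(x_pre_c))) / 2)
  d_pre <- mean(as.numeric(x_pre_t)) - mean(as.numeric(x_pre_c))
  d_post <- mean(as.numeric(x_t)) - mean(as.numeric(x_c))
  if (!is.finite(s) || s == 0) {
    return(c(smd_pre = 0, smd_post = 0, zero_sd = 1))
  }
  c(smd_pre = d_pre / s, smd_post = d_post / s, zero_sd = 0)
}

#' Covariate balance before and after matching
#'
#' Standardised mean differences per covariate: difference in group means (or
#' level proportions, one row per non-reference level of a categorical)
#' divided by the pooled pre-match standard deviation. Reported both on the
#' full cohort (pre) and on the matched pairs (post). A covariate with zero
#' pooled SD is reported as SMD 0 and flagged.
#'
#' @param cohort patient data frame containing both groups.
#' @param pairs a [match_optimal()] result.
#' @param covariates covariate names (default: matching covariates).
#' @return data frame with columns covariate, smd_pre, smd_post, zero_sd.
#' @export
balance_table <- function(cohort, pairs, covariates = .matching_covariates) {
  stopifnot(inherits(pairs, "matched_pairs"))
  pre_t <- cohort[cohort$group == "bondy", , drop = FALSE]
  pre_c <- cohort[cohort$group == "soc", , drop = FALSE]
  post_t <- cohort[match(pairs$pairs$treated_id, cohort$id), , drop = FALSE]
  post_c <- cohort[match(pairs$pairs$control_id, cohort$id), , drop = FALSE]
  rows <- list()
  for (f in covariates) {
    v <- cohort[[f]]
    if (is.factor(v)) {
      for (lev in levels(v)[-1]) {
        r <- .smd_one(post_t[[f]] == lev, post_c[[f]] == lev,
                      pre_t[[f]] == lev, pre_c[[f]] == lev)
        rows[[paste0(f, ":", lev)]] <- r
      }
    } else {
      rows[[f]] <- .smd_one(post_t[[f]], post_c[[f]], pre_t[[f]], pre_c[[f]])
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  out$covariate <- names(rows)
  rownames(out) <- NULL
  out[, c("covariate", "smd_pre", "smd_post", "zero_sd")]
}

#' Export matching artefacts
#'
#' Writes the pairs as CSV (treated_id, control_id, distance) and the
#' balance table as CSV (covariate, smd_pre, smd_post).
#'
#' @param pairs a [match_optimal()] result.
#' @param balance a [balance_table()] result (optional).
#' @param pairs_path,balance_path output paths.
#' @return invisibly `NULL`.
#' @export
export_matching <- function(pairs, balance = NULL,
                            pairs_path = NULL, balance_path = NULL) {
  if (!is.null(pairs_path)) {
    write.csv(pairs$pairs, pairs_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(balance) && !is.null(balance_path)) {
    write.csv(balance, balance_path, row.names = FALSE, quote = FALSE)
  }
  invisible(NULL)
}
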