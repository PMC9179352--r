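# BCLC staging and treatment-allocation adherence accounting.

# Vectorised staging over a patient data frame. Rules (non-metastatic,
# Child A/B population; Child C excluded upstream):
#   advanced      : vascular invasion or performance status >= 1
#   intermediate  : >= 4 nodules, or 2-3 nodules with largest > 3 cm
#   very early    : single nodule <= 2 cm, Child A, PS 0
#   early         : everything else
.stage_vec <- function(cohort) {
  if (any(as.character(cohort$child_pugh) == "C", na.rm = TRUE)) {
    stop("domain error: Child-Pugh C patients are outside the staged population", call. = FALSE)
  }
  n <- nrow(cohort)
  adv <- cohort$vascular_invasion | cohort$performance_status >= 1
  multi <- as.character(cohort$n_tumors_cat)
  big <- as.character(cohort$largest_mm_cat) != "le30"
  inter <- !adv & (multi == "ge4" | (multi == "2_3" & big))
  mm <- cohort$largest_mm
  if (is.null(mm)) mm <- ifelse(as.character(cohort$largest_mm_cat) == "le30", 25, 45)
  ve <- !adv & !inter & multi == "1" & mm <= 20 &
    as.character(cohort$child_pugh) == "A" & cohort$performance_status == 0
  out <- rep("early", n)
  out[inter] <- "intermediate"
  out[adv] <- "advanced"
  out[ve] <- "very_early"
  out
}

#' Derive the BCLC stage of a patient
#'
#' Deterministic staging from covariates: advanced if vascular invasion or
#' performance status >= 1; otherwise intermediate if four or more nodules or
#' a multinodular tumour beyond up-to-three-nodules-under-3-cm; otherwise
#' very early if a single nodule of at most 2 cm in a Child A, PS 0 patient;
#' otherwise early. Child C input is a domain error (excluded population).
#'
#' @param patient a one-row patient data frame (or a full cohort, in which
#'   case a vector of stages is returned).
#' @return character stage(s): `"very_early"`, `"early"`, `"intermediate"`
#'   or `"advanced"`.
#' @export
stage_bclc <- function(patient) {
  st <- .stage_vec(patient)
  if (nrow(patient) == 1) st[[1]] else st
}

#' First-line arms counted guideline-adherent for a stage
#'
#' Very early and early map to the curative options (resection, ablation);
#' intermediate to TACE; advanced to sorafenib (TARE is grouped with
#' sorafenib in this model).
#'
#' @param stage one of the four BCLC stages.
#' @return character vector of adherent first-line arms.
#' @export
guideline_arms <- function(stage) {
  stage <- match.arg(stage, .levels$stage)
  switch(stage,
    very_early = c("resection", "ablation"),
    early = c("resection", "ablation"),
    intermediate = "tace",
    advanced = "sorafenib"
  )
}

# round half away from zero to integer (printed-percent convention)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Guideline-adherence report for a cohort
#'
#' Stages every patient, counts first-line treatments adherent to the
#' stage-recommended arms, and counts palliative stage migration: earlier
#' stage (very early or early) patients whose first-line treatment is TACE or
#' sorafenib. Percentages are rounded half away from zero to integer percent.
#'
#' @param cohort patient data frame.
#' @return an object of class `adherence_report`: list with
#'   `per_stage_adherent` (stage, adherent, total, pct), `overall_adherent`,
#'   `overall_adherent_pct`, `migration_count`, `migration_pct`, `n`.
#' @export
adherence_report <- function(cohort) {
  n <- nrow(cohort)
  if (n == 0) {
    return(structure(list(
      per_stage_adherent = data.frame(stage = .levels$stage, adherent = 0L,
                                      total = 0L, pct = NA_real_),
      overall_adherent = 0L, overall_adherent_pct = NA_real_,
      migration_count = 0L, migration_pct = NA_real_, n = 0L,
      undefined = TRUE), class = "adherence_report"))
  }
  st <- .stage_vec(cohort)
  arm <- as.character(cohort$first_line)
  adherent <- mapply(function(s, a) a %in% guideline_arms(s), st, arm)
  per <- data.frame(stage = .levels$stage, adherent = NA_integer_,
                    total = NA_integer_, pct = NA_real_)
  for (i in seq_along(.levels$stage)) {
    s <- .levels$stage[i]
    tot <- sum(st == s)
    adh <- sum(adherent & st == s)
    per$adherent[i] <- adh; per$total[i] <- tot
    per$pct[i] <- if (tot > 0) round_half_away(100 * adh / tot) else NA_real_
  }
  # collapse very early + early for the earlier-stage row used in reporting
  earlier <- st %in% c("very_early", "early")
  migration <- earlier & arm %in% c("tace", "sorafenib")
  structure(list(
    per_stage_adherent = per,
    earlier_stage_adherent = sum(adherent & earlier),
    earlier_stage_total = sum(earlier),
    overall_adherent = sum(adherent),
    overall_adherent_pct = round_half_away(100 * sum(adherent) / n),
    migration_count = sum(migration),
    migration_pct = round_half_away(100 * sum(migration) / n),
    n = n, undefined = FALSE
  ), class = "adherence_report")
}

#' @export
print.adherence_report <- function(x, ...) {
  cat("BCLC adherence report (n =", x$n, ")\n")
  if (x$undefined) {
    cat("  empty cohort: percentages undefined\n")
    return(invisible(x))
  }
  print(x$per_stage_adherent, row.names = FALSE)
  cat(sprintf("  overall adherent: %d/%d (%d%%)\n",
              x$overall_adherent, x$n, x$overall_adherent_pct))
  cat(sprintf("  palliative stage migration: %d (%d%%)\n",
              x$migration_count, x$migration_pct))
  invisible(x)
}

#' First-line allocation summary
#'
#' Counts and integer percents per first-line arm, overall and by BCLC
#' stage, plus the curative (resection + ablation) share. Percents are
#' computed on the cohort size and rounded half away from zero.
#'
#' @param cohort patient data frame.
#' @return list with `overall` (arm, count, pct), `by_stage` (stage, arm,
#'   count, pct), `curative_count`, `curative_pct`, `n`.
#' @export
allocation_summary <- function(cohort) {
  n <- nrow(cohort)
  arms <- .levels$first_line
  if (n == 0) {
    overall <- data.frame(arm = arms, count = 0L, pct = NA_real_)
    return(list(overall = overall,
                by_stage = data.frame(stage = character(0), arm = character(0),
                                      count = integer(0), pct = numeric(0)),
                curative_count = 0L, curative_pct = NA_real_, n = 0L))
  }
  st <- .stage_vec(cohort)
  arm <- as.character(cohort$first_line)
  overall <- data.frame(
    arm = arms,
    count = as.integer(table(factor(arm, arms))),
    stringsAsFactors = FALSE
  )
  overall$pct <- round_half_away(100 * overall$count / n)
  tab <- table(factor(st, .levels$stage), factor(arm, arms))
  by_stage <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(by_stage) <- c("stage", "arm", "count")
  by_stage$pct <- round_half_away(100 * by_stage$count / n)
  cur <- sum(arm %in% c("resection", "ablation"))
  list(overall = overall, by_stage = by_stage,
       curative_count = cur, curative_pct = round_half_away(100 * cur / n),
       n = n)
}

#' Export an adherence/allocation report
#'
#' Writes the allocation summary as a tidy CSV (stage, arm, count, percent)
#' and the adherence report as JSON.
#'
#' @param cohort patient data frame.
#' @param csv_path,json_path output file paths (either may be `NULL` to
#'   skip).
#' @return invisibly, a list with the two report objects.
#' @export
export_adherence <- function(cohort, csv_path = NULL, json_path = NULL) {
  alloc <- allocation_summary(cohort)
  rep <- adherence_report(cohort)
  if (!is.null(csv_path)) {
    write.csv(alloc$by_stage, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      n = rep$n,
      per_stage = rep$per_stage_adherent,
      overall_adherent_pct = rep$overall_adherent_pct,
      migration_count = rep$migration_count,
      migration_pct = rep$migration_pct
    ), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(allocation = alloc, adherence = rep))
}
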