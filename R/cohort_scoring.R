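#' Read a patient cohort from CSV
#'
#' One row per patient. Required predictor columns: `bmi`, `smoker`,
#' `disease_course_gt2y`, `psa`, `higher_relief`, `faster_relief`,
#' `prior_biologics`, `treatment_months`; optional `patient_id`,
#' `relapsed` and `followup_days` (needed for validation, not for pure
#' scoring). Boolean columns accept 0/1, true/false, yes/no.
#'
#' @param path path to a UTF-8 comma-separated file with a header row.
#' @return a validated cohort data frame with logical flag columns.
#' @export
read_cohort <- function(path) {
  stop_if(!file.exists(path), "cohort file not found: ", path)
  validate_cohort_table(utils::read.csv(path, stringsAsFactors = FALSE,
                                        encoding = "UTF-8"))
}

predictor_fields <- c("bmi", "smoker", "disease_course_gt2y", "psa",
                      "higher_relief", "faster_relief", "prior_biologics",
                      "treatment_months")
flag_fields <- c("smoker", "disease_course_gt2y", "psa", "higher_relief",
                 "faster_relief", "prior_biologics")

#' Validate a cohort table
#'
#' Checks the eight predictors are present and complete, BMI lies in
#' the (10, 70) kg/m2 plausibility window, treatment course is
#' positive, and — when outcomes are carried — that `relapsed` rows have
#' a `followup_days` within the 183-day design horizon.
#'
#' @param df a cohort data frame (see [read_cohort()]).
#' @return the data frame with flags coerced to logical.
#' @export
validate_cohort_table <- function(df) {
  miss <- setdiff(predictor_fields, names(df))
  stop_if(length(miss) > 0, "cohort missing predictor column(s): ",
          paste(miss, collapse = ", "))
  if (is.null(df$patient_id)) df$patient_id <- sprintf("p%04d", seq_len(nrow(df)))
  for (f in flag_fields) {
    df[[f]] <- parse_flag(df[[f]])
    stop_if(anyNA(df[[f]]), "missing values in predictor '", f, "'")
  }
  stop_if(!is.numeric(df$bmi) || anyNA(df$bmi), "bmi must be numeric, complete")
  stop_if(any(df$bmi <= 10 | df$bmi >= 70),
          "bmi outside the plausibility window (10, 70) kg/m2")
  stop_if(!is.numeric(df$treatment_months) || anyNA(df$treatment_months) ||
            any(df$treatment_months <= 0), "treatment_months must be positive")
  if (!is.null(df$relapsed)) {
    df$relapsed <- parse_flag(df$relapsed)
    has <- !is.na(df$relapsed)
    stop_if(any(has & is.na(df$followup_days %||% rep(NA_real_, nrow(df)))),
            "rows with a relapse indicator need followup_days")
    if (any(has)) {
      stop_if(any(df$followup_days[has] < 0 | df$followup_days[has] > 183),
              "followup_days must lie in [0, 183] for the 6-month design")
    }
  }
  df
}

# evaluate one stratum predicate over a vector of field values
eval_predicate <- function(op, value, value2, x) {
  switch(op,
         lt = x < value,
         le = x <= value,
         gt = x > value,
         ge = x >= value,
         between = x >= value & x < value2,
         eq_true = x == TRUE,
         eq_false = x == FALSE,
         stop("unknown predicate op: ", op))
}

#' Score a cohort with a stratified score table
#'
#' Each factor contributes the points of the single stratum whose
#' predicate matches the patient; the total score is their sum. Risk
#' groups are assigned from the total with [assign_risk_group()].
#'
#' @param cohort a validated cohort data frame (see [read_cohort()]).
#' @param table a [score_table]; default the canonical published table.
#' @param cutpoints strictly increasing risk-group cutpoints, default
#'   `c(6, 11.25, 17.5)`.
#' @return the cohort with one `pts_<factor>` column per factor, a
#'   `total_score` column and a `risk_group` factor.
#' @examples
#' p <- data.frame(bmi = 25, smoker = TRUE, disease_course_gt2y = TRUE,
#'                 psa = FALSE, higher_relief = TRUE, faster_relief = FALSE,
#'                 prior_biologics = FALSE, treatment_months = 11)
#' score_cohort(p)$total_score  # 1.5 + 1 + 5 + 5 = 12.5
#' @export
score_cohort <- function(cohort, table = canonical_score_table(),
                         cutpoints = c(6, 11.25, 17.5)) {
  cohort <- validate_cohort_table(cohort)
  items <- table$items
  pts <- matrix(NA_real_, nrow(cohort), 0)
  for (fid in unique(items$factor_id)) {
    strata <- items[items$factor_id == fid, , drop = FALSE]
    hit <- rep(NA_real_, nrow(cohort))
    nhit <- rep(0L, nrow(cohort))
    for (j in seq_len(nrow(strata))) {
      m <- eval_predicate(strata$op[j], strata$value[j], strata$value2[j],
                          cohort[[strata$field[j]]])
      hit[m] <- strata$points[j]
      nhit <- nhit + as.integer(m)
    }
    stop_if(any(nhit != 1L),
            "strata of factor '", fid, "' did not match exactly once")
    pts <- cbind(pts, hit)
    colnames(pts)[ncol(pts)] <- paste0("pts_", fid)
  }
  out <- cbind(cohort, as.data.frame(pts))
  out$total_score <- rowSums(pts)
  out$risk_group <- assign_risk_group(out$total_score, cutpoints)
  out
}

#' Assign risk groups from total scores
#'
#' Groups are the half-open intervals `[0, c1]`, `(c1, c2]`, `(c2, c3]`
#' and `(c3, Inf)` on the score line — a boundary score belongs to the
#' lower-indexed group, so the default upper cutpoint of the
#' intermediate group (11.25) is itself classed intermediate,
#' consistent with "score above the cutoff predicts relapse".
#'
#' @param total_score numeric scores.
#' @param cutpoints strictly increasing triple, default `c(6, 11.25, 17.5)`.
#' @return an ordered factor with levels `low`, `intermediate`, `high`,
#'   `very_high`.
#' @export
assign_risk_group <- function(total_score, cutpoints = c(6, 11.25, 17.5)) {
  stop_if(length(cutpoints) != 3 || any(diff(cutpoints) <= 0),
          "cutpoints must be three strictly increasing values")
  cut(total_score, breaks = c(-Inf, cutpoints, Inf),
      labels = c("low", "intermediate", "high", "very_high"),
      right = TRUE, ordered_result = TRUE)
}

#' Write a scored cohort to CSV
#'
#' @param scored output of [score_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scored_cohort <- function(scored, path) {
  utils::write.csv(scored, path, row.names = FALSE)
  invisible(path)
}
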