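#' ROC analysis of a risk score against a binary outcome
#'
#' AUC and its 95% CI come from [pROC::roc()] with the DeLong variance
#' method; the AUC equals the pairwise concordance statistic with ties
#' counted one half. The ROC curve is traced over all thresholds;
#' cutoff candidates are the midpoints between consecutive distinct
#' observed scores, the optimal cutoff maximises Youden's
#' J = sensitivity + specificity - 1, and exact ties are broken toward
#' the higher-specificity (larger) cutoff.
#'
#' @param scores numeric risk scores.
#' @param outcomes logical (or 0/1) event indicators; both classes must
#'   be present.
#' @return a list of class `roc_result`: `auc`, `auc_ci_low`,
#'   `auc_ci_high`, `optimal_cutoff`, `youden_j`,
#'   `sensitivity_at_cutoff`, `specificity_at_cutoff`, and `roc_points`
#'   (data frame of fpr/tpr from (0,0) to (1,1)).
#' @export
roc_analysis <- function(scores, outcomes) {
  outcomes <- as.logical(outcomes)
  stop_if(length(scores) != length(outcomes), "length mismatch")
  stop_if(anyNA(scores) || anyNA(outcomes), "missing values not allowed")
  stop_if(!any(outcomes) || all(outcomes),
          "both outcome classes must be present")

  r <- pROC::roc(response = outcomes, predictor = scores,
                 direction = "<", levels = c(FALSE, TRUE), quiet = TRUE)
  # on a perfectly separated cohort the DeLong interval collapses to 1-1;
  # pROC warns about it, but the degenerate interval is the right answer
  ci <- as.numeric(suppressWarnings(pROC::ci.auc(r, method = "delong")))

  # exhaustive scan over midpoint cutoffs: predict relapse when score > c
  dist <- sort(unique(scores))
  cand <- if (length(dist) > 1) (dist[-1] + dist[-length(dist)]) / 2 else dist
  npos <- sum(outcomes); nneg <- sum(!outcomes)
  sens <- vapply(cand, function(cc) sum(scores > cc & outcomes) / npos,
                 numeric(1))
  spec <- vapply(cand, function(cc) sum(scores <= cc & !outcomes) / nneg,
                 numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(spec[best] + 1e-9 * cand[best])]

  ord <- order(-cand)
  roc_points <- data.frame(fpr = c(0, 1 - spec[ord], 1),
                           tpr = c(0, sens[ord], 1))
  structure(list(auc = as.numeric(pROC::auc(r)),
                 auc_ci_low = max(0, ci[1]), auc_ci_high = min(1, ci[3]),
                 optimal_cutoff = cand[best], youden_j = j[best],
                 sensitivity_at_cutoff = sens[best],
                 specificity_at_cutoff = spec[best],
                 roc_points = roc_points),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f); cutoff %g: sens %.3f, spec %.3f\n",
              x$auc, x$auc_ci_low, x$auc_ci_high, x$optimal_cutoff,
              x$sensitivity_at_cutoff, x$specificity_at_cutoff))
  invisible(x)
}

#' Logistic calibration of score to relapse probability
#'
#' Decision-curve analysis needs predicted probabilities while the
#' point score is unitless; the default mapping is a univariable
#' logistic regression of outcome on score, which is monotone
#' increasing in the score whenever the fitted slope is positive.
#'
#' @param scores,outcomes as in [roc_analysis()].
#' @return a function mapping score values to probabilities in (0, 1).
#' @export
score_to_probability_default <- function(scores, outcomes) {
  outcomes <- as.logical(outcomes)
  stop_if(!any(outcomes) || all(outcomes),
          "degenerate cohort: both outcome classes required for calibration")
  fit <- stats::glm(outcomes ~ scores, family = stats::binomial())
  co <- stats::coef(fit)
  function(s) stats::plogis(co[1] + co[2] * s)
}

#' Decision curve analysis (net benefit)
#'
#' At each threshold probability t, the net benefit of the model is
#' `TP/n - (FP/n) * t/(1-t)` where a patient is predicted positive when
#' the mapped probability is at least t. Reference curves: treat-all
#' (`prevalence - (1-prevalence) * t/(1-t)`) and treat-none (0).
#'
#' @param scores,outcomes as in [roc_analysis()].
#' @param score_to_probability monotone score-to-probability mapping;
#'   default the logistic calibration fitted on this cohort.
#' @param thresholds threshold grid in (0,1); default 0.254 to 0.597 in
#'   steps of 0.001, the 6-month relapse-rate range reported across
#'   discontinuation studies.
#' @return a data frame of class `dca_curve`: `threshold`,
#'   `net_benefit_model`, `net_benefit_all`, `net_benefit_none`.
#' @export
dca <- function(scores, outcomes, score_to_probability = NULL,
                thresholds = seq(0.254, 0.597, by = 0.001)) {
  outcomes <- as.logical(outcomes)
  stop_if(length(thresholds) == 0, "empty threshold grid")
  stop_if(any(thresholds <= 0 | thresholds >= 1),
          "thresholds must lie in (0, 1)")
  if (is.null(score_to_probability))
    score_to_probability <- score_to_probability_default(scores, outcomes)
  p <- score_to_probability(scores)
  n <- length(outcomes)
  prev <- mean(outcomes)
  nb <- vapply(thresholds, function(t) {
    pos <- p >= t
    sum(pos & outcomes) / n - sum(pos & !outcomes) / n * t / (1 - t)
  }, numeric(1))
  out <- data.frame(threshold = thresholds,
                    net_benefit_model = nb,
                    net_benefit_all = prev - (1 - prev) * thresholds /
                      (1 - thresholds),
                    net_benefit_none = 0)
  class(out) <- c("dca_curve", "data.frame")
  out
}

#' Kaplan-Meier risk-group stratification with hazard-ratio contrasts
#'
#' Product-limit relapse-free curves per risk group
#' ([survival::survfit()]); the cumulative relapse risk is
#' 1 - S(t). Group contrasts come from a proportional-hazards
#' regression on the group indicators with the low-risk group as
#' reference ([survival::coxph()], Efron tie handling), reported as
#' hazard ratios with 95% Wald CIs and two-sided p-values.
#'
#' @param scored a scored cohort (see [score_cohort()]) carrying
#'   `relapsed`, `followup_days` and `risk_group`.
#' @return a list of class `km_strata`: `survfit` (the fitted
#'   product-limit curves), `curves` (tidy per-group step data with
#'   cumulative risk), `hazard_ratios` (per non-reference group), and
#'   `n_events`.
#' @export
km_strata <- function(scored) {
  stop_if(is.null(scored$relapsed) || is.null(scored$followup_days),
          "scored cohort must carry relapsed and followup_days")
  stop_if(is.null(scored$risk_group), "scored cohort must carry risk_group")
  event <- as.integer(as.logical(scored$relapsed))
  time <- scored$followup_days
  stop_if(any(time < 0), "follow-up times must be nonnegative")
  stop_if(sum(event) == 0, "at least one relapse event is required")
  grp <- droplevels(factor(scored$risk_group,
                           levels = c("low", "intermediate", "high",
                                      "very_high"), ordered = FALSE))
  empty <- setdiff(c("low", "intermediate", "high", "very_high"), levels(grp))
  if (length(empty) > 0)
    warning("risk group(s) with no members dropped from contrasts: ",
            paste(empty, collapse = ", "))

  fit <- survival::survfit(survival::Surv(time, event) ~ grp)
  sm <- summary(fit, censored = TRUE)
  gnames <- if (is.null(sm$strata)) rep(levels(grp)[1], length(sm$time)) else
    sub("^grp=", "", as.character(sm$strata))
  curves <- data.frame(risk_group = gnames, time = sm$time,
                       n_risk = sm$n.risk, n_event = sm$n.event,
                       survival = sm$surv, cumulative_risk = 1 - sm$surv)

  hr <- NULL
  if (nlevels(grp) > 1) {
    ref_events <- sum(event[grp == levels(grp)[1]])
    if (ref_events == 0) {
      warning("no events in the reference (lowest) risk group; ",
              "hazard ratios undefined")
    } else {
      cox <- survival::coxph(survival::Surv(time, event) ~ grp,
                             ties = "efron")
      co <- summary(cox)$coefficients
      hr <- data.frame(risk_group = sub("^grp", "", rownames(co)),
                       hr = exp(co[, "coef"]),
                       ci_low = exp(co[, "coef"] - Z95 * co[, "se(coef)"]),
                       ci_high = exp(co[, "coef"] + Z95 * co[, "se(coef)"]),
                       p_value = co[, "Pr(>|z|)"],
                       stringsAsFactors = FALSE)
      rownames(hr) <- NULL
    }
  }
  structure(list(survfit = fit, curves = curves, hazard_ratios = hr,
                 n_events = sum(event)),
            class = "km_strata")
}

#' Full validation report for a scored cohort
#'
#' Runs the ROC/Youden analysis, decision-curve analysis and
#' Kaplan-Meier risk-group stratification, and packages the results.
#'
#' @param scored a scored cohort with outcomes (see [score_cohort()]).
#' @param dca_range two-element threshold range for the decision curve,
#'   default `c(0.254, 0.597)`.
#' @param dca_step threshold grid step, default 0.001.
#' @return a list of class `validation_report` with elements `roc`,
#'   `dca`, `km`, `n`, `prevalence`.
#' @export
validate_cohort <- function(scored, dca_range = c(0.254, 0.597),
                            dca_step = 0.001) {
  stop_if(is.null(scored$total_score), "cohort must be scored first")
  stop_if(is.null(scored$relapsed), "validation requires the relapse outcome")
  y <- as.logical(scored$relapsed)
  s <- scored$total_score
  structure(list(
    roc = roc_analysis(s, y),
    dca = dca(s, y, thresholds = seq(dca_range[1], dca_range[2],
                                     by = dca_step)),
    km = km_strata(scored),
    n = length(y),
    prevalence = mean(y)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation report (n = %d, relapse prevalence %.3f)\n",
              x$n, x$prevalence))
  print(x$roc)
  if (!is.null(x$km$hazard_ratios)) {
    cat("Hazard ratios vs low-risk:\n")
    print(x$km$hazard_ratios, row.names = FALSE)
  }
  inb <- mean(x$dca$net_benefit_model >
                pmax(x$dca$net_benefit_all, 0))
  cat(sprintf("Decision curve above both references on %.0f%% of the %.3f-%.3f band\n",
              100 * inb, min(x$dca$threshold), max(x$dca$threshold)))
  invisible(x)
}

#' Write a validation report to JSON
#'
#' @param report a `validation_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  r <- report$roc
  out <- list(
    n = report$n,
    prevalence = report$prevalence,
    roc = list(auc = r$auc, auc_ci_low = r$auc_ci_low,
               auc_ci_high = r$auc_ci_high,
               optimal_cutoff = r$optimal_cutoff,
               sensitivity = r$sensitivity_at_cutoff,
               specificity = r$specificity_at_cutoff,
               points = r$roc_points),
    dca = as.data.frame(report$dca),
    km = list(curves = report$km$curves,
              hazard_ratios = report$km$hazard_ratios,
              n_events = report$km$n_events)
  )
  jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
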