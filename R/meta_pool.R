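#' Read per-study effect sizes from CSV
#'
#' One row per extracted study effect. Required columns: `study_id`,
#' `factor_id`, `effect_type` (one of `"OR"`, `"RR"`, `"HR"`), `estimate`,
#' `ci_low`, `ci_high`, `n`. Optional: `baseline_risk` (control-group event
#' proportion, used for OR-to-RR conversion), `adjustment_rank` and
#' `followup_months` (used by [dedup_study_effects()]).
#'
#' @param path path to a UTF-8, comma-separated file with a header row.
#' @return a validated data frame of study effects.
#' @seealso [convert_to_rr()], [pool_effects()]
#' @export
read_study_effects <- function(path) {
  stop_if(!file.exists(path), "study-effects file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  validate_study_effects(df)
}

#' Validate a study-effects table
#'
#' Checks column presence, positivity of the three ratio values, the
#' `ci_low < estimate < ci_high` ordering, and that any `baseline_risk`
#' lies in (0, 1).
#'
#' @param df a data frame of study effects (see [read_study_effects()]).
#' @return the data frame, invisibly unchanged except for type coercion.
#' @export
validate_study_effects <- function(df) {
  need <- c("study_id", "factor_id", "effect_type", "estimate", "ci_low",
            "ci_high", "n")
  miss <- setdiff(need, names(df))
  stop_if(length(miss) > 0, "missing column(s): ", paste(miss, collapse = ", "))
  df$effect_type <- toupper(trimws(df$effect_type))
  bad <- !df$effect_type %in% c("OR", "RR", "HR")
  stop_if(any(bad), "effect_type must be OR, RR or HR; got: ",
          paste(unique(df$effect_type[bad]), collapse = ", "))
  for (col in c("estimate", "ci_low", "ci_high")) {
    stop_if(!is.numeric(df[[col]]) || any(!is.finite(df[[col]])) ||
              any(df[[col]] <= 0), "column '", col, "' must be positive")
  }
  stop_if(any(df$ci_low >= df$estimate) || any(df$estimate >= df$ci_high),
          "need ci_low < estimate < ci_high on every row")
  stop_if(any(df$n <= 0 | df$n != round(df$n)),
          "n must be a positive integer")
  if (!is.null(df$baseline_risk)) {
    br <- df$baseline_risk[!is.na(df$baseline_risk)]
    stop_if(length(br) > 0 && (any(br <= 0) || any(br >= 1)),
            "baseline_risk must lie in (0, 1)")
  }
  df
}

#' Deduplicate multiple effect estimates per study and factor
#'
#' When a study reports several effect values for the same risk factor,
#' keep the estimate with the most adjusted covariates, breaking ties by
#' the longest follow-up, then by lexicographic `study_id` row order.
#' Rows lacking `adjustment_rank`/`followup_months` are treated as rank 0.
#'
#' @param df a study-effects data frame.
#' @return the filtered data frame, one row per (study_id, factor_id).
#' @export
dedup_study_effects <- function(df) {
  rank <- df$adjustment_rank %||% rep(0, nrow(df))
  fup <- df$followup_months %||% rep(0, nrow(df))
  rank[is.na(rank)] <- 0
  fup[is.na(fup)] <- 0
  key <- paste(df$study_id, df$factor_id, sep = "\r")
  ord <- order(key, -rank, -fup, as.character(df$study_id))
  df <- df[ord, , drop = FALSE]
  df[!duplicated(key[ord]), , drop = FALSE]
}

#' Convert extracted effect sizes to the relative-risk scale
#'
#' RR rows pass through unchanged; HR is taken as RR over the fixed
#' 6-month horizon; OR is converted with the Zhang-Yu formula
#' \deqn{RR = OR / ((1 - p_0) + p_0 \cdot OR)}
#' applied to the estimate and both confidence bounds, where \eqn{p_0}
#' is the study's control-group event proportion (`baseline_risk`), or
#' `default_p0` when absent.
#'
#' @param df a validated study-effects data frame.
#' @param default_p0 baseline risk used for OR rows without their own
#'   `baseline_risk`; default 0.447, the validation cohort's 6-month
#'   relapse proportion.
#' @return the data frame with all rows on the RR scale; a `converted_from`
#'   column records the original effect type of each row.
#' @examples
#' eff <- data.frame(study_id = "s1", factor_id = "smoking",
#'                   effect_type = "OR", estimate = 2, ci_low = 1.5,
#'                   ci_high = 2.67, n = 100L, baseline_risk = 0.5)
#' convert_to_rr(eff)$estimate  # 2 / (0.5 + 0.5 * 2) = 1.3333
#' @export
convert_to_rr <- function(df, default_p0 = 0.447) {
  df <- validate_study_effects(df)
  stop_if(!is_prob(default_p0), "default_p0 must lie in (0, 1)")
  p0 <- df$baseline_risk %||% rep(NA_real_, nrow(df))
  p0[is.na(p0)] <- default_p0
  stop_if(any(df$effect_type == "OR" & (p0 <= 0 | p0 >= 1)),
          "OR conversion needs baseline risk in (0, 1)")
  or2rr <- function(or, p) or / ((1 - p) + p * or)
  is_or <- df$effect_type == "OR"
  df$converted_from <- df$effect_type
  df$estimate[is_or] <- or2rr(df$estimate[is_or], p0[is_or])
  df$ci_low[is_or] <- or2rr(df$ci_low[is_or], p0[is_or])
  df$ci_high[is_or] <- or2rr(df$ci_high[is_or], p0[is_or])
  df$effect_type <- "RR"
  df
}

#' Standard error of a log effect from a 95% confidence interval
#'
#' Inverts a Wald 95% CI on the log scale:
#' `(log(ci_high) - log(ci_low)) / (2 * 1.959964)`.
#'
#' @param ci_low,ci_high positive confidence bounds, `ci_low <= ci_high`.
#' @return the nonnegative standard error of the log effect (vectorised).
#' @export
log_se_from_ci <- function(ci_low, ci_high) {
  stop_if(any(!is.finite(ci_low)) || any(!is.finite(ci_high)) ||
            any(ci_low <= 0) || any(ci_high <= 0),
          "confidence bounds must be positive")
  stop_if(any(ci_low > ci_high), "need ci_low <= ci_high")
  (log(ci_high) - log(ci_low)) / (2 * Z95)
}

#' Pool same-factor study effects with a heterogeneity-gated model
#'
#' Inverse-variance pooling of log relative risks. A fixed-effects fit
#' supplies Cochran's Q (k - 1 df), its chi-square p-value and I-squared;
#' the between-study variance tau-squared is the DerSimonian-Laird moment
#' estimator. The model is chosen by the heterogeneity gate: random
#' effects when `q_pvalue < 0.10` or `i_squared > 50`, fixed otherwise.
#' Fitting is delegated to [metafor::rma()] (`method = "FE"` / `"DL"`).
#'
#' @param df study effects for a single factor, all on the RR scale
#'   (see [convert_to_rr()]); at least two rows.
#' @param force_model optionally `"fixed"` or `"random"` to override the
#'   gate (sensitivity analysis); the result is flagged as forced.
#' @return a one-row data frame with `factor_id`, pooled `rr`, `ci_low`,
#'   `ci_high`, `q_stat`, `q_pvalue`, `i_squared`, `tau_squared`,
#'   `model`, `k_studies`, `forced`.
#' @export
pool_effects <- function(df, force_model = NULL) {
  stop_if(nrow(df) < 2,
          "pooling needs >= 2 studies; pass single studies through unpooled")
  stop_if(length(unique(df$factor_id)) != 1,
          "all studies must share one factor_id; got: ",
          paste(unique(df$factor_id), collapse = ", "))
  stop_if(!all(df$effect_type == "RR"),
          "effects must be on the RR scale; run convert_to_rr() first")
  if (!is.null(force_model))
    force_model <- match.arg(force_model, c("fixed", "random"))

  yi <- log(df$estimate)
  sei <- log_se_from_ci(df$ci_low, df$ci_high)
  stop_if(any(sei == 0), "degenerate CI (zero width) cannot be weighted")
  fe <- metafor::rma(yi = yi, sei = sei, method = "FE")
  dl <- metafor::rma(yi = yi, sei = sei, method = "DL")

  k <- length(yi)
  q <- as.numeric(fe$QE)
  q_p <- as.numeric(fe$QEp)
  i2 <- max(0, (q - (k - 1)) / q) * 100
  if (!is.finite(i2)) i2 <- 0  # q == 0

  gate_random <- (q_p < 0.10) || (i2 > 50)
  model <- force_model %||% if (gate_random) "random" else "fixed"
  fit <- if (model == "random") dl else fe
  b <- as.numeric(fit$b)
  se <- as.numeric(fit$se)

  data.frame(
    factor_id = df$factor_id[1],
    rr = exp(b),
    ci_low = exp(b - Z95 * se),
    ci_high = exp(b + Z95 * se),
    q_stat = q,
    q_pvalue = q_p,
    i_squared = i2,
    tau_squared = as.numeric(dl$tau2),
    model = model,
    k_studies = k,
    forced = !is.null(force_model),
    stringsAsFactors = FALSE
  )
}

#' Sensitivity analysis: repool under the alternative model
#'
#' Same computation as [pool_effects()] with the model forced, so the
#' robustness of a pooled RR to the fixed/random choice can be reported.
#'
#' @inheritParams pool_effects
#' @param forced_model `"fixed"` or `"random"`.
#' @return as [pool_effects()], with `forced = TRUE`.
#' @export
sensitivity_switch <- function(df, forced_model) {
  pool_effects(df, force_model = forced_model)
}

#' Pool every risk factor in a study-effects table
#'
#' @param df a study-effects data frame on the RR scale, possibly several
#'   factors; single-study factors pass through with their own CI and
#'   `model = NA`.
#' @param force_model optional override applied to every factor.
#' @return a data frame with one row per factor, as [pool_effects()].
#' @export
pool_all <- function(df, force_model = NULL) {
  out <- lapply(split(df, df$factor_id), function(d) {
    if (nrow(d) == 1) {
      data.frame(factor_id = d$factor_id, rr = d$estimate,
                 ci_low = d$ci_low, ci_high = d$ci_high,
                 q_stat = 0, q_pvalue = NA_real_, i_squared = 0,
                 tau_squared = 0, model = NA_character_, k_studies = 1L,
                 forced = FALSE, stringsAsFactors = FALSE)
    } else {
      pool_effects(d, force_model = force_model)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Collinearity screen for the final model factors
#'
#' Keeps factors whose pooled 95% CI lies on one side of the null
#' (statistical significance on the ratio scale; a bound printed
#' exactly at 1.00, as rounded CIs sometimes are, still counts as
#' one-sided), then resolves overlapping
#' predictors by dropping the redundant member of each collinear pair
#' (by default: weight in favour of BMI, disease duration in years in
#' favour of the binary duration > 2 years).
#'
#' @param pooled a pooled-effects data frame (`factor_id`, `rr`,
#'   `ci_low`, `ci_high`, ...).
#' @param collinear named character vector: `drop = keep` pairs; the
#'   named factor is dropped when the value factor is also present.
#' @return the screened pooled-effects data frame.
#' @export
select_model_factors <- function(pooled,
                                 collinear = c(weight = "bmi",
                                               disease_course_years = "disease_course")) {
  sig <- (pooled$ci_low >= 1 & pooled$rr > 1) |
    (pooled$ci_high <= 1 & pooled$rr < 1)
  kept <- pooled[sig, , drop = FALSE]
  for (drop in names(collinear)) {
    if (drop %in% kept$factor_id && collinear[[drop]] %in% kept$factor_id)
      kept <- kept[kept$factor_id != drop, , drop = FALSE]
  }
  rownames(kept) <- NULL
  kept
}

#' Write pooled effects to CSV or JSON
#'
#' @param pooled a pooled-effects data frame.
#' @param path output path; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_pooled_effects <- function(pooled, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(pooled, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(pooled, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read pooled effects from CSV or JSON
#'
#' @param path file written by [write_pooled_effects()] or a hand-built
#'   table with at least `factor_id`, `rr`, `ci_low`, `ci_high`.
#' @return a pooled-effects data frame.
#' @export
read_pooled_effects <- function(path) {
  stop_if(!file.exists(path), "pooled-effects file not found: ", path)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  }
  need <- c("factor_id", "rr", "ci_low", "ci_high")
  miss <- setdiff(need, names(df))
  stop_if(length(miss) > 0, "missing column(s): ", paste(miss, collapse = ", "))
  stop_if(any(df$rr <= 0 | df$ci_low <= 0 | df$ci_high <= 0),
          "pooled ratios must be positive")
  df
}
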