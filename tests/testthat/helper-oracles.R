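# Independent oracles, kept deliberately naive: step-by-step formula
# transcriptions and brute-force enumerations against which the package
# implementations are checked.

# DerSimonian-Laird pooling, spelled out term by term on the log scale
dl_pool_oracle <- function(yi, sei) {
  z <- 1.959964
  vi <- sei^2
  wi <- 1 / vi
  y_fixed <- sum(wi * yi) / sum(wi)
  q <- sum(wi * (yi - y_fixed)^2)
  k <- length(yi)
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
  cc <- sum(wi) - sum(wi^2) / sum(wi)
  tau2 <- max(0, (q - (k - 1)) / cc)
  wr <- 1 / (vi + tau2)
  y_random <- sum(wr * yi) / sum(wr)
  se_f <- sqrt(1 / sum(wi))
  se_r <- sqrt(1 / sum(wr))
  list(q = q, q_p = stats::pchisq(q, k - 1, lower.tail = FALSE), i2 = i2,
       tau2 = tau2,
       fixed = c(rr = exp(y_fixed), lo = exp(y_fixed - z * se_f),
                 hi = exp(y_fixed + z * se_f)),
       random = c(rr = exp(y_random), lo = exp(y_random - z * se_r),
                  hi = exp(y_random + z * se_r)))
}

# study-effects data frame from log effects and standard errors
effects_from_logs <- function(yi, sei, factor_id = "f") {
  z <- 1.959964
  data.frame(study_id = paste0("s", seq_along(yi)), factor_id = factor_id,
             effect_type = "RR", estimate = exp(yi),
             ci_low = exp(yi - z * sei), ci_high = exp(yi + z * sei),
             n = 100L, stringsAsFactors = FALSE)
}

# pairwise concordance with ties counted one half (brute force, O(n^2))
auc_concordance_oracle <- function(scores, outcomes) {
  pos <- scores[as.logical(outcomes)]
  neg <- scores[!as.logical(outcomes)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# exhaustive Youden search over midpoints of consecutive distinct scores;
# ties resolved toward the higher-specificity (larger) cutoff
youden_oracle <- function(scores, outcomes) {
  outcomes <- as.logical(outcomes)
  d <- sort(unique(scores))
  cand <- if (length(d) > 1) (d[-1] + d[-length(d)]) / 2 else d
  best <- NULL
  for (cc in cand) {
    sens <- mean(scores[outcomes] > cc)
    spec <- mean(scores[!outcomes] <= cc)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec))
      best <- list(cutoff = cc, j = j, sens = sens, spec = spec)
  }
  best
}

# a tiny deterministic scored cohort with outcomes, for KM/Cox tests
make_scored <- function(total_score, relapsed, followup_days,
                        cutpoints = c(6, 11.25, 17.5)) {
  data.frame(patient_id = sprintf("t%03d", seq_along(total_score)),
             total_score = total_score,
             risk_group = assign_risk_group(total_score, cutpoints),
             relapsed = relapsed, followup_days = followup_days,
             stringsAsFactors = FALSE)
}

# one fully specified patient record; override fields as needed
make_patient <- function(...) {
  base <- data.frame(bmi = 22, smoker = FALSE, disease_course_gt2y = FALSE,
                     psa = FALSE, higher_relief = FALSE,
                     faster_relief = FALSE, prior_biologics = FALSE,
                     treatment_months = 12, stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}
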