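test_that("effect conversion to the RR scale", {
  # RR passes through untouched, HR is taken as RR at the 6-month horizon
  rr_in <- data.frame(study_id = "s", factor_id = "f", effect_type = "RR",
                      estimate = 1.5, ci_low = 1.1, ci_high = 2.0, n = 50L)
  out <- convert_to_rr(rr_in)
  expect_equal(out[, c("estimate", "ci_low", "ci_high")],
               rr_in[, c("estimate", "ci_low", "ci_high")])
  expect_equal(out$converted_from, "RR")

  hr_in <- transform(rr_in, effect_type = "HR")
  expect_equal(convert_to_rr(hr_in)$estimate, 1.5)
  expect_equal(convert_to_rr(hr_in)$converted_from, "HR")

  # Zhang-Yu: RR = OR / ((1 - p0) + p0 * OR); hand value for OR 2, p0 0.5
  or_in <- data.frame(study_id = "s", factor_id = "f", effect_type = "OR",
                      estimate = 2.0, ci_low = 1.5, ci_high = 2.67, n = 50L,
                      baseline_risk = 0.5)
  expect_equal(convert_to_rr(or_in)$estimate, 2 / (0.5 + 0.5 * 2),
               tolerance = 1e-12)

  # a null odds ratio is conversion-invariant for any baseline risk
  for (p0 in c(0.1, 0.447, 0.9)) {
    null_or <- data.frame(study_id = "s", factor_id = "f",
                          effect_type = "OR", estimate = 1,
                          ci_low = 0.8, ci_high = 1.25, n = 50L,
                          baseline_risk = p0)
    expect_equal(convert_to_rr(null_or)$estimate, 1, tolerance = 1e-12)
  }

  # conversion direction: OR further from 1 than the RR it implies
  no_p0 <- data.frame(study_id = "s", factor_id = "f", effect_type = "OR",
                      estimate = 2.0, ci_low = 1.5, ci_high = 2.67, n = 50L)
  expect_lt(convert_to_rr(no_p0)$estimate, 2.0)  # default p0 = 0.447 applied

  bad <- transform(or_in, baseline_risk = 1.2)
  expect_error(convert_to_rr(bad), "baseline_risk")
})

test_that("log standard error from a 95% confidence interval", {
  expect_equal(log_se_from_ci(1, 1), 0)
  # hand evaluation for the CI 1.23-2.36
  expect_equal(log_se_from_ci(1.23, 2.36), 0.166240, tolerance = 1e-5)
  # closed form: a CI of (1/e, e) spans 2 log units
  expect_equal(log_se_from_ci(exp(-1), exp(1)), 1 / 1.959964,
               tolerance = 1e-12)
  expect_error(log_se_from_ci(0, 2), "positive")
  expect_error(log_se_from_ci(2, 1), "ci_low")
})

test_that("pooling matches the step-by-step DerSimonian-Laird oracle", {
  # frozen fixture: yi = log(1.4, 2.0, 0.9), sei = (0.2, 0.25, 0.3);
  # expected values computed independently with dl_pool_oracle
  yi <- log(c(1.4, 2.0, 0.9)); sei <- c(0.2, 0.25, 0.3)
  eff <- effects_from_logs(yi, sei)
  p <- pool_effects(eff)
  expect_equal(p$q_stat, 4.1923346998, tolerance = 1e-9)
  expect_equal(p$i_squared, 52.2938853121, tolerance = 1e-9)
  expect_equal(p$tau_squared, 0.0667665568, tolerance = 1e-9)
  # the I2 > 50 gate selects random effects (Q p-value is 0.123)
  expect_gt(p$q_pvalue, 0.10)
  expect_identical(p$model, "random")
  expect_equal(p$rr, 1.3964753050, tolerance = 1e-6)
  expect_equal(p$ci_low, 0.9319081511, tolerance = 1e-6)
  expect_equal(p$ci_high, 2.0926346391, tolerance = 1e-6)

  # oracle equivalence on random small study sets, fixed and random routes
  set.seed(401)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    yi <- stats::rnorm(k, 0.3, 0.4)
    sei <- stats::runif(k, 0.05, 0.4)
    o <- dl_pool_oracle(yi, sei)
    eff <- effects_from_logs(yi, sei)
    pf <- pool_effects(eff, force_model = "fixed")
    pr <- pool_effects(eff, force_model = "random")
    expect_equal(pf$rr, unname(o$fixed["rr"]), tolerance = 1e-6)
    expect_equal(pf$ci_low, unname(o$fixed["lo"]), tolerance = 1e-6)
    expect_equal(pf$ci_high, unname(o$fixed["hi"]), tolerance = 1e-6)
    expect_equal(pr$rr, unname(o$random["rr"]), tolerance = 1e-6)
    expect_equal(pr$tau_squared, o$tau2, tolerance = 1e-6)
    expect_equal(pf$q_stat, o$q, tolerance = 1e-6)
    expect_equal(pf$q_pvalue, o$q_p, tolerance = 1e-6)
    expect_equal(pf$i_squared, o$i2, tolerance = 1e-6)
    # structural invariants
    expect_true(pf$i_squared >= 0 && pf$i_squared <= 100)
    expect_gte(pf$q_stat, 0)
    expect_gte(pr$tau_squared, 0)
    # fixed pooled log-RR is a convex combination of study log-RRs
    expect_gte(log(pf$rr), min(yi) - 1e-12)
    expect_lte(log(pf$rr), max(yi) + 1e-12)
    # random-effects interval is at least as wide as the fixed one
    expect_gte(log(pr$ci_high / pr$ci_low), log(pf$ci_high / pf$ci_low) - 1e-12)
  }
})

test_that("pooling degenerate and gated cases", {
  # identical studies: zero heterogeneity, fixed model, same estimate
  eff <- effects_from_logs(rep(log(2), 2), rep(0.15, 2))
  p <- pool_effects(eff)
  expect_equal(p$rr, 2, tolerance = 1e-9)
  expect_equal(p$q_stat, 0, tolerance = 1e-12)
  expect_equal(p$i_squared, 0)
  expect_identical(p$model, "fixed")

  # equal variances: pooled log-RR is the arithmetic mean of study log-RRs
  yi <- log(c(1.2, 1.5, 1.9))
  p <- pool_effects(effects_from_logs(yi, rep(0.2, 3)),
                    force_model = "fixed")
  expect_equal(log(p$rr), mean(yi), tolerance = 1e-12)

  # all-null studies pool to exactly RR 1
  p <- pool_effects(effects_from_logs(rep(0, 3), c(0.1, 0.2, 0.3)))
  expect_equal(p$rr, 1, tolerance = 1e-12)

  # strongly heterogeneous set trips the p < 0.10 arm of the gate
  p <- pool_effects(effects_from_logs(c(-0.5, 0.9, 0.1), rep(0.1, 3)))
  expect_lt(p$q_pvalue, 0.10)
  expect_identical(p$model, "random")

  expect_error(pool_effects(effects_from_logs(0.2, 0.1)), ">= 2")
  mixed <- rbind(effects_from_logs(c(0.1, 0.2), c(0.1, 0.1), "a"),
                 effects_from_logs(0.3, 0.1, "b"))
  expect_error(pool_effects(mixed), "factor_id")
})

test_that("sensitivity analysis by model switch", {
  # homogeneous studies: tau2 truncates at 0, forced random == fixed
  hom <- effects_from_logs(c(0.18, 0.22, 0.20), rep(0.3, 3))
  pf <- pool_effects(hom, force_model = "fixed")
  pr <- sensitivity_switch(hom, "random")
  expect_equal(pr$tau_squared, 0)
  expect_equal(pr$rr, pf$rr, tolerance = 1e-12)
  expect_true(pr$forced)
  expect_identical(pr$model, "random")
  # forcing fixed always reports fixed, even under heterogeneity
  het <- effects_from_logs(c(-0.5, 0.9, 0.1), rep(0.1, 3))
  expect_identical(sensitivity_switch(het, "fixed")$model, "fixed")
})

test_that("deduplication keeps the most adjusted, longest-followed estimate", {
  df <- data.frame(
    study_id = c("s1", "s1", "s1", "s2"),
    factor_id = "smoking",
    effect_type = "RR",
    estimate = c(1.2, 1.3, 1.4, 1.1),
    ci_low = c(1.0, 1.1, 1.2, 1.0) - 0.05,
    ci_high = c(1.5, 1.6, 1.7, 1.3),
    n = 100L,
    adjustment_rank = c(1, 2, 2, 1),
    followup_months = c(12, 6, 12, 6),
    stringsAsFactors = FALSE)
  out <- dedup_study_effects(df)
  expect_equal(nrow(out), 2)
  # s1 keeps rank 2 with the longer follow-up (estimate 1.4)
  expect_equal(out$estimate[out$study_id == "s1"], 1.4)
})

test_that("collinearity screen keeps exactly the significant, non-overlapping factors", {
  reported <- read_pooled_effects(
    system.file("extdata", "pooled_effects_reported.csv",
                package = "psorelapse"))
  extra <- read_pooled_effects(
    system.file("extdata", "collinear_factors_synthetic.csv",
                package = "psorelapse"))
  screened <- select_model_factors(rbind(reported, extra))
  expect_equal(nrow(screened), 8)
  expect_setequal(screened$factor_id,
                  c("bmi", "smoking", "disease_course", "psa",
                    "faster_relief", "higher_relief", "prior_biologics",
                    "treatment_course"))
  # a non-significant factor is screened out before the collinearity step
  ns <- data.frame(factor_id = "alcohol", rr = 1.1, ci_low = 0.9,
                   ci_high = 1.35, source = "synthetic")
  expect_false("alcohol" %in%
                 select_model_factors(rbind(reported, ns))$factor_id)
})

test_that("study-effects IO validates and round-trips", {
  path <- system.file("extdata", "study_effects_synthetic.csv",
                      package = "psorelapse")
  eff <- read_study_effects(path)
  expect_true(all(eff$effect_type %in% c("OR", "RR", "HR")))
  pooled <- pool_all(convert_to_rr(dedup_study_effects(eff)))
  expect_equal(sort(unique(pooled$factor_id)), sort(unique(eff$factor_id)))
  expect_true(all(pooled$ci_low < pooled$rr & pooled$rr < pooled$ci_high))

  tmp <- tempfile(fileext = ".json")
  write_pooled_effects(pooled, tmp)
  back <- read_pooled_effects(tmp)
  expect_equal(back$rr, pooled$rr, tolerance = 1e-12)

  bad <- eff; bad$ci_low[1] <- bad$ci_high[1] + 1
  expect_error(validate_study_effects(bad), "ci_low")
})
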