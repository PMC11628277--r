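#' Configuration for the end-to-end pipeline
#'
#' Paths and options tying the stages together: meta-analytic pooling
#' (or a pre-pooled input), score-table derivation and verification,
#' cohort scoring, and the validation report.
#'
#' @param out_dir output directory (created if absent).
#' @param cohort_path CSV of patient records; when `NULL` a synthetic
#'   cohort of size `synthetic_n` is generated.
#' @param study_effects_path optional CSV of per-study effects to pool;
#'   mutually exclusive with `pooled_path`.
#' @param pooled_path optional CSV/JSON of already-pooled effects;
#'   default the packaged pooled relative risks of the eight model
#'   factors.
#' @param rounding rounding policy for the derived table's binary
#'   factors.
#' @param cutpoints risk-group cutpoints.
#' @param dca_range decision-curve threshold range.
#' @param seed seed used for any synthetic generation.
#' @param synthetic_n synthetic cohort size when `cohort_path` is NULL.
#' @param invert_remission_factors score with the remission points on
#'   the "No" strata (see [canonical_score_table()]).
#' @param default_p0 baseline risk for OR-to-RR conversion.
#' @param force_model optional pooling-model override.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            cohort_path = NULL,
                            study_effects_path = NULL,
                            pooled_path = NULL,
                            rounding = "nearest_integer",
                            cutpoints = c(6, 11.25, 17.5),
                            dca_range = c(0.254, 0.597),
                            seed = 1,
                            synthetic_n = 416,
                            invert_remission_factors = FALSE,
                            default_p0 = 0.447,
                            force_model = NULL) {
  stop_if(missing(out_dir) || !nzchar(out_dir), "out_dir is required")
  for (p in c(cohort_path, study_effects_path, pooled_path))
    stop_if(!is.null(p) && !file.exists(p), "input path not found: ", p)
  stop_if(length(cutpoints) != 3 || any(diff(cutpoints) <= 0),
          "cutpoints must be strictly increasing")
  structure(list(out_dir = out_dir, cohort_path = cohort_path,
                 study_effects_path = study_effects_path,
                 pooled_path = pooled_path, rounding = rounding,
                 cutpoints = cutpoints, dca_range = dca_range,
                 seed = as.integer(seed), synthetic_n = synthetic_n,
                 invert_remission_factors = invert_remission_factors,
                 default_p0 = default_p0, force_model = force_model),
            class = "pipeline_config")
}

#' Run the full relapse-risk pipeline
#'
#' Stages: (1) pool per-study effects (or load pooled ones) and apply
#' the collinearity screen; (2) derive the point table from the pooled
#' RRs and verify it against the canonical table; (3) score the cohort
#' (from file, or synthetic) with the canonical table and assign risk
#' groups; (4) produce the validation report (ROC, DCA, KM/HR). All
#' stage outputs and a run manifest are written under `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with `pooled`, `derived_table`,
#'   `verification`, `scored`, `report`, and the manifest.
#' @export
run_pipeline <- function(config) {
  stop_if(!inherits(config, "pipeline_config"), "need a pipeline_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  # stage 1: pooled effects
  if (!is.null(config$study_effects_path)) {
    eff <- read_study_effects(config$study_effects_path)
    eff <- dedup_study_effects(eff)
    eff <- convert_to_rr(eff, default_p0 = config$default_p0)
    pooled <- pool_all(eff, force_model = config$force_model)
  } else {
    path <- config$pooled_path %||%
      system.file("extdata", "pooled_effects_reported.csv",
                  package = "psorelapse", mustWork = TRUE)
    pooled <- read_pooled_effects(path)
  }
  pooled <- select_model_factors(pooled)
  write_pooled_effects(pooled, out("pooled_effects.csv"))

  # stage 2: derived table + verification against the canonical table
  canonical <- canonical_score_table(config$invert_remission_factors)
  derived <- build_derived_table(pooled, rounding = config$rounding)
  verification <- verify_against_canonical(derived, canonical_score_table())
  write_score_table(derived, out("derived_table.json"))
  jsonlite::write_json(verification, out("table_verification.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  # stage 3: cohort scoring (canonical table is authoritative for points)
  cohort <- if (!is.null(config$cohort_path)) {
    read_cohort(config$cohort_path)
  } else {
    generate_cohort(generator_config(n = config$synthetic_n,
                                     seed = config$seed),
                    table = canonical)
  }
  scored <- score_cohort(cohort, table = canonical,
                         cutpoints = config$cutpoints)
  write_scored_cohort(scored, out("scored_cohort.csv"))

  # stage 4: validation
  report <- NULL
  if (!is.null(scored$relapsed)) {
    report <- validate_cohort(scored, dca_range = config$dca_range)
    write_validation_report(report, out("validation_report.json"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("psorelapse")),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    n_patients = nrow(scored),
    n_factors = length(unique(pooled$factor_id)),
    table_verification_pass = verification$pass,
    outputs = c("pooled_effects.csv", "derived_table.json",
                "table_verification.json", "scored_cohort.csv",
                if (!is.null(report)) "validation_report.json")
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(pooled = pooled, derived_table = derived,
                 verification = verification, scored = scored,
                 report = report, manifest = manifest))
}
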