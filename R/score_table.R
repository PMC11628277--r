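#' Construct a stratified score table
#'
#' A score table maps each risk factor to mutually exclusive strata, each
#' carrying a point weight in steps of 0.5. Strata are machine-readable
#' predicates on patient-record fields: `op` is one of `lt`, `le`, `gt`,
#' `ge` (threshold on `value`), `between` (`value <= x < value2`),
#' `eq_true`, `eq_false` (boolean flags).
#'
#' @param items data frame with columns `factor_id`, `stratum_label`,
#'   `field`, `op`, `value`, `value2` (numeric, NA where unused),
#'   `points`, and optionally `raw_points` (unrounded |10 beta| scale,
#'   kept by [build_derived_table()] for verification).
#' @param version_tag free-text version label.
#' @param provenance `"canonical"` or `"derived"`.
#' @return an object of class `score_table`.
#' @export
score_table <- function(items, version_tag = "unversioned",
                        provenance = c("canonical", "derived")) {
  provenance <- match.arg(provenance)
  need <- c("factor_id", "stratum_label", "field", "op", "points")
  miss <- setdiff(need, names(items))
  stop_if(length(miss) > 0, "items missing column(s): ",
          paste(miss, collapse = ", "))
  stop_if(!all(items$op %in% c("lt", "le", "gt", "ge", "between",
                               "eq_true", "eq_false")),
          "unknown predicate op")
  stop_if(any(items$points < 0), "points must be nonnegative")
  stop_if(any(abs(items$points * 2 - round(items$points * 2)) > 1e-9),
          "points must be multiples of 0.5")
  # every factor needs a zero-point reference stratum; a factor with a
  # null pooled effect may legitimately have all strata at zero
  ref <- tapply(items$points, items$factor_id, function(p) sum(p == 0))
  stop_if(any(ref < 1),
          "each factor needs a zero-point reference stratum: ",
          paste(names(ref)[ref < 1], collapse = ", "))
  if (is.null(items$value)) items$value <- NA_real_
  if (is.null(items$value2)) items$value2 <- NA_real_
  structure(list(items = items, version_tag = version_tag,
                 provenance = provenance),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %s (%s): %d factors, max total %g\n",
              x$version_tag, x$provenance,
              length(unique(x$items$factor_id)), max_total_score(x)))
  print(x$items[, c("factor_id", "stratum_label", "points")], row.names = FALSE)
  invisible(x)
}

#' Maximum / minimum achievable total score
#'
#' Sum over factors of the largest (respectively smallest) stratum points.
#'
#' @param table a [score_table].
#' @return a single number.
#' @export
max_total_score <- function(table) {
  sum(tapply(table$items$points, table$items$factor_id, max))
}

#' @rdname max_total_score
#' @export
min_total_score <- function(table) {
  sum(tapply(table$items$points, table$items$factor_id, min))
}

#' The canonical relapse-risk score table
#'
#' The published eight-factor point system shipped with the package:
#' BMI (three strata at 24 and 28 kg/m2), smoking, disease course
#' > 2 years, psoriatic arthritis, higher lesion relief (PASI 90
#' achieved), faster lesion relief (PASI 75 within 8 weeks), previous
#' biologic exposure, and treatment course (threshold 10.75 months,
#' with the shorter course scored). Totals range 0 to 23.5 in steps
#' of 0.5.
#'
#' The two lesion-relief factors are pooled as protective (RR < 1) yet
#' the published table awards their points to the "Yes" strata; the
#' table is shipped exactly as printed. Set `invert_remission = TRUE`
#' to move those points to the "No" strata (the risk-direction
#' encoding) instead; both variants are documented, neither asserted
#' as the published intent.
#'
#' @param invert_remission move the higher/faster relief points to the
#'   "No" strata (default `FALSE`: as printed).
#' @return a [score_table] with `provenance = "canonical"`.
#' @export
canonical_score_table <- function(invert_remission = FALSE) {
  path <- system.file("extdata", "canonical_score_table.json",
                      package = "psorelapse", mustWork = TRUE)
  tab <- read_score_table(path)
  if (invert_remission) {
    it <- tab$items
    for (fid in c("higher_relief", "faster_relief")) {
      sel <- it$factor_id == fid
      it$points[sel] <- rev(it$points[sel])
    }
    tab$items <- it
    tab$version_tag <- paste0(tab$version_tag, "+inverted-remission")
  }
  tab
}

#' Serialize / deserialize a score table as JSON
#'
#' The round-trip `read_score_table(write_score_table(x, f))` is the
#' identity on items, version tag and provenance.
#'
#' @param table a [score_table].
#' @param path file path (JSON).
#' @return `write_score_table` returns `path` invisibly;
#'   `read_score_table` returns a [score_table].
#' @export
write_score_table <- function(table, path) {
  jsonlite::write_json(
    list(version_tag = table$version_tag, provenance = table$provenance,
         items = table$items),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  stop_if(!file.exists(path), "score-table file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  items <- as.data.frame(obj$items)
  if (is.null(items$value)) items$value <- NA_real_
  if (is.null(items$value2)) items$value2 <- NA_real_
  score_table(items, version_tag = obj$version_tag %||% "unversioned",
              provenance = obj$provenance %||% "derived")
}

#' Log relative risk (beta coefficient)
#'
#' The per-factor model weight is the natural log of the pooled RR.
#'
#' @param rr positive relative risk (vectorised).
#' @return `log(rr)`.
#' @export
beta_from_rr <- function(rr) {
  stop_if(any(!is.finite(rr)) || any(rr <= 0), "rr must be positive")
  log(rr)
}

#' Point weight from a beta coefficient
#'
#' Points are `|10 * beta|`, rounded either to the nearest integer or to
#' the nearest half point (ties round up). The absolute value encodes
#' that a protective factor (beta < 0) scores its risk-direction
#' stratum.
#'
#' @param beta log relative risk (vectorised).
#' @param rounding `"nearest_integer"` or `"nearest_half"`.
#' @return nonnegative points.
#' @export
points_from_beta <- function(beta,
                             rounding = c("nearest_integer", "nearest_half")) {
  rounding <- match.arg(rounding)
  x <- abs(10 * beta)
  if (rounding == "nearest_integer") round_half_up(x) else round_to_half(x)
}

#' Derive a score table from pooled relative risks
#'
#' Binary factors get one scored stratum with [points_from_beta()]
#' applied to the pooled log RR. BMI, pooled per kg/m2, is stratified:
#' each non-reference stratum scores `|10 * log(rr) * delta|` where
#' `delta` is its configured unit offset from the reference stratum.
#' The treatment-course factor scores its short-course stratum
#' (<= 10.75 months); the longer course is the reference. The unrounded
#' |10 beta|-scale value of every stratum is kept in `raw_points` for
#' [verify_against_canonical()].
#'
#' @param pooled pooled-effects data frame containing all eight model
#'   factors (`bmi`, `smoking`, `disease_course`, `psa`,
#'   `higher_relief`, `faster_relief`, `prior_biologics`,
#'   `treatment_course`).
#' @param bmi_strata_offsets numeric vector of unit offsets for the two
#'   scored BMI strata, default `c(5, 10)` (24-27.99 and >= 28 kg/m2
#'   relative to the < 24 reference).
#' @param rounding rounding policy for binary factors and BMI
#'   (`"nearest_integer"` for binary factors in the published table);
#'   BMI and treatment course use `"nearest_half"` granularity
#'   regardless, matching the published half-point entries.
#' @return a [score_table] with `provenance = "derived"`.
#' @export
build_derived_table <- function(pooled, bmi_strata_offsets = c(5, 10),
                                rounding = c("nearest_integer",
                                             "nearest_half")) {
  rounding <- match.arg(rounding)
  canon <- canonical_score_table()
  need <- unique(canon$items$factor_id)
  miss <- setdiff(need, pooled$factor_id)
  stop_if(length(miss) > 0, "pooled effects missing factor(s): ",
          paste(miss, collapse = ", "))
  stop_if(length(bmi_strata_offsets) != 2 || any(bmi_strata_offsets <= 0),
          "bmi_strata_offsets must be two positive offsets")

  rr_of <- function(fid) pooled$rr[match(fid, pooled$factor_id)]
  items <- canon$items
  items$raw_points <- 0
  for (fid in need) {
    sel <- which(items$factor_id == fid)
    beta <- beta_from_rr(rr_of(fid))
    if (fid == "bmi") {
      # reference stratum first, then the two scored strata in order
      raw <- c(0, abs(10 * beta * bmi_strata_offsets))
      pts <- round_to_half(raw)
    } else if (fid == "treatment_course") {
      raw <- ifelse(items$points[sel] > 0, abs(10 * beta), 0)
      pts <- round_to_half(raw)
    } else {
      raw <- ifelse(items$points[sel] > 0, abs(10 * beta), 0)
      pts <- points_from_beta(ifelse(items$points[sel] > 0, beta, 0),
                              rounding = rounding)
    }
    items$raw_points[sel] <- raw
    items$points[sel] <- pts
  }
  score_table(items, version_tag = "derived-from-pooled",
              provenance = "derived")
}

#' Verify a derived score table against the canonical one
#'
#' Compares the derived table's unrounded |10 beta|-scale stratum values
#' (`raw_points`, falling back to `points`) with the canonical points.
#' Passes when every absolute discrepancy is below `tol`.
#'
#' @param derived,canonical [score_table]s over the same factors/strata.
#' @param tol maximum tolerated absolute discrepancy (default 0.5, half
#'   the coarser rounding step).
#' @return a list with `pass` (logical) and `discrepancies` (per-stratum
#'   data frame with the absolute gaps, largest first).
#' @export
verify_against_canonical <- function(derived, canonical, tol = 0.5) {
  di <- derived$items
  ci <- canonical$items
  key <- function(x) paste(x$factor_id, x$stratum_label, sep = "\r")
  stop_if(!setequal(key(di), key(ci)),
          "derived and canonical tables have different strata")
  di <- di[match(key(ci), key(di)), , drop = FALSE]
  raw <- di$raw_points %||% di$points
  gap <- abs(raw - ci$points)
  rep <- data.frame(factor_id = ci$factor_id,
                    stratum_label = ci$stratum_label,
                    derived_raw = raw, canonical_points = ci$points,
                    abs_gap = gap, stringsAsFactors = FALSE)
  rep <- rep[order(-rep$abs_gap), ]
  rownames(rep) <- NULL
  list(pass = all(gap < tol), tol = tol, discrepancies = rep)
}
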