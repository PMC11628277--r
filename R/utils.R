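# shared internal helpers

# 95% Wald quantile used throughout (fixed confidence level)
Z95 <- 1.959964

#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' @noRd
round_to_half <- function(x) floor(2 * x + 0.5) / 2

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# strict scalar checks used by the validating constructors
#' @noRd
stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

#' @noRd
is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x > 0 & x < 1)

# booleans in cohort CSVs arrive as 0/1, true/false, yes/no (any case)
#' @noRd
parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    stop_if(!all(x %in% c(0, 1) | is.na(x)), "numeric flag must be 0/1")
    return(x == 1)
  }
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("1", "true", "yes", "y")] <- TRUE
  out[s %in% c("0", "false", "no", "n")] <- FALSE
  bad <- !is.na(s) & s != "" & is.na(out)
  stop_if(any(bad), "unrecognised flag value(s): ",
          paste(unique(s[bad]), collapse = ", "))
  out
}
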