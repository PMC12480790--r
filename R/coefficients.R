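#' Construct a coefficient set for the withdrawal model
#'
#' Bundles the intercept and nine criterion coefficients of the
#' stated-preference logit utility with the two parameters of the log-time
#' baseline withdrawal probability. The defaults are the published group
#' estimates from the clinical vignette study; [default_coefficients()]
#' returns them directly.
#'
#' @param intercept Utility intercept (default -1.61).
#' @param betas Named numeric vector of nine criterion coefficients; names
#'   must match [criterion_names()] (symbol aliases accepted).
#' @param baseline_intercept Intercept of the baseline withdrawal
#'   probability in time (default -1.2861).
#' @param baseline_slope Coefficient on `log(cid_months)` in the baseline
#'   (default 0.7557).
#'
#' @return An object of class `coefficient_set`.
#' @export
#' @examples
#' coefficient_set()           # published defaults
#' default_coefficients()
coefficient_set <- function(intercept = -1.61,
                            betas = c(
                              slow_response     = 0.55,
                              rf_positive       = 0.57,
                              flare_history     = 1.36,
                              joint_damage      = 0.87,
                              uveitis_history   = 1.28,
                              spine_involvement = 0.75,
                              tmj_involvement   = 0.35,
                              treatment_failure = 1.09,
                              prefer_continue   = 1.85
                            ),
                            baseline_intercept = -1.2861,
                            baseline_slope = 0.7557) {
  canonical <- unname(criterion_names())
  if (is.null(names(betas))) {
    stop(config_error("betas must be a named vector of criterion coefficients"))
  }
  mapped <- canonicalize_criterion(names(betas))
  if (anyNA(mapped)) {
    stop(config_error(paste0(
      "unknown criterion name(s) in betas: ",
      paste(names(betas)[is.na(mapped)], collapse = ", ")
    )))
  }
  if (anyDuplicated(mapped)) {
    stop(config_error("duplicate criterion names in betas"))
  }
  missing <- setdiff(canonical, mapped)
  if (length(missing) > 0) {
    stop(config_error(paste0(
      "betas must cover all nine criteria; missing: ",
      paste(missing, collapse = ", ")
    )))
  }
  betas <- stats::setNames(as.numeric(betas), mapped)[canonical]
  for (p in c("intercept", "baseline_intercept", "baseline_slope")) {
    v <- get(p)
    if (length(v) != 1L || !is.numeric(v) || !is.finite(v)) {
      stop(config_error(paste0(p, " must be a single finite number")))
    }
  }
  if (!all(is.finite(betas))) {
    stop(config_error("all betas must be finite"))
  }
  if (sum(betas) <= 0) {
    stop(config_error("sum of betas must be positive"))
  }
  structure(
    list(
      intercept = as.numeric(intercept),
      betas = betas,
      baseline_intercept = as.numeric(baseline_intercept),
      baseline_slope = as.numeric(baseline_slope)
    ),
    class = "coefficient_set"
  )
}

#' @rdname coefficient_set
#' @export
default_coefficients <- function() coefficient_set()

#' Read a coefficient configuration from JSON
#'
#' The file is a JSON object with keys `intercept`, `betas` (a mapping of
#' the nine criterion names to values), `baseline_intercept`, and
#' `baseline_slope`. The packaged default
#' (`system.file("extdata", "default_coefficients.json", package =
#' "jiawithdraw")`) reproduces the published model exactly.
#'
#' @param path Path to a JSON file (or a JSON string).
#' @return A [coefficient_set()].
#' @export
read_coefficients <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  needed <- c("intercept", "betas", "baseline_intercept", "baseline_slope")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    stop(config_error(paste0(
      "coefficient config is missing: ", paste(missing, collapse = ", ")
    )))
  }
  coefficient_set(
    intercept = x$intercept,
    betas = unlist(x$betas),
    baseline_intercept = x$baseline_intercept,
    baseline_slope = x$baseline_slope
  )
}

#' Write a coefficient set to JSON
#'
#' @param coeffs A [coefficient_set()].
#' @param path Output file path; if `NULL` the JSON text is returned.
#' @return The JSON text, invisibly when written to a file.
#' @export
write_coefficients <- function(coeffs, path = NULL) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  txt <- jsonlite::toJSON(
    list(
      intercept = coeffs$intercept,
      betas = as.list(coeffs$betas),
      baseline_intercept = coeffs$baseline_intercept,
      baseline_slope = coeffs$baseline_slope
    ),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# Short content hash of a coefficient set, for run logs.
coefficient_hash <- function(coeffs) {
  v <- c(coeffs$intercept, coeffs$betas,
         coeffs$baseline_intercept, coeffs$baseline_slope)
  s <- paste(sprintf("%.17g", v), collapse = ",")
  # polynomial rolling hash over the serialized values; enough to make a
  # changed configuration visible in run logs
  h <- 0
  for (b in utf8ToInt(s)) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat("<coefficient_set> (hash ", coefficient_hash(x), ")\n", sep = "")
  cat("  utility: ", x$intercept, " + ",
      paste(sprintf("%g*%s", x$betas, names(x$betas)), collapse = " + "),
      "\n", sep = "")
  cat("  baseline: ", x$baseline_intercept, " + ", x$baseline_slope,
      " * log(cid_months)\n", sep = "")
  invisible(x)
}
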