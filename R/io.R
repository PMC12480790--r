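PROFILE_FIELDS <- c("cid_months", "patient_id", "notes")

model_version <- function() {
  tryCatch(as.character(utils::packageVersion("jiawithdraw")),
           error = function(e) "unknown")
}

# Shared validation path for a single record coming from JSON or a CSV row.
# Every page-1 field of the prototype was mandatory, so a missing criterion
# is an input error, never imputed. Unknown keys are routed into notes.
record_to_profile <- function(rec, where = "record") {
  canonical <- unname(criterion_names())
  nms <- names(rec)
  mapped <- canonicalize_criterion(nms)
  is_flag <- !is.na(mapped)
  is_known <- is_flag | nms %in% PROFILE_FIELDS
  problems <- character(0)

  if (!("cid_months" %in% nms) || is_blank(rec[["cid_months"]])) {
    problems <- c(problems, "missing required field 'cid_months'")
  }
  flags <- stats::setNames(rep(NA_real_, 9), canonical)
  for (i in which(is_flag)) {
    v <- rec[[i]]
    if (is_blank(v)) {
      problems <- c(problems,
                    sprintf("missing value for criterion '%s'", mapped[i]))
      next
    }
    v <- suppressWarnings(as.numeric(v))
    if (is.na(v) || !(v %in% c(0, 1))) {
      problems <- c(problems, sprintf(
        "criterion '%s' must be exactly 0 or 1 (got '%s')",
        mapped[i], as.character(rec[[i]])
      ))
    } else {
      flags[mapped[i]] <- v
    }
  }
  absent <- canonical[!canonical %in% mapped[is_flag]]
  if (length(absent) > 0) {
    problems <- c(problems, sprintf("missing required criterion '%s'", absent))
  }
  cid <- suppressWarnings(as.numeric(rec[["cid_months"]]))
  if (!is.null(rec[["cid_months"]]) && !is_blank(rec[["cid_months"]])) {
    if (is.na(cid)) {
      problems <- c(problems, "cid_months must be a number")
    } else if (cid < CID_DOMAIN[1] || cid > CID_DOMAIN[2]) {
      problems <- c(problems, sprintf(
        "cid_months = %g is outside the supported domain [%g, %g] months",
        cid, CID_DOMAIN[1], CID_DOMAIN[2]
      ))
    }
  }
  extras <- rec[!is_known]
  extras <- extras[!vapply(extras, is_blank, logical(1))]
  notes <- rec[["notes"]]
  if (length(extras) > 0) {
    notes <- c(if (!is.null(notes) && !is_blank(notes)) list(notes = notes),
               extras)
  }
  if (length(problems) > 0) {
    stop(validation_error(paste0(where, ": ", problems)))
  }
  # range/flag checks (all-at-once) happen in the constructor
  withCallingHandlers(
    do.call(criterion_profile, c(
      list(cid_months = cid),
      as.list(flags),
      list(
        patient_id = if (!is_blank(rec[["patient_id"]]))
          as.character(rec[["patient_id"]]) else NULL,
        notes = if (length(notes) > 0) notes else NULL
      )
    )),
    jiawithdraw_validation_error = function(e) {
      stop(validation_error(paste0(where, ": ", e$problems)))
    }
  )
}

is_blank <- function(v) {
  is.null(v) || length(v) == 0 ||
    (length(v) == 1 && (is.na(v) || identical(trimws(as.character(v)), "")))
}

#' Read a single patient profile from JSON
#'
#' The record must contain `cid_months` and all nine criteria (canonical
#' names or symbol aliases); every criterion is mandatory. Keys outside
#' the schema are collected into the profile's `notes` as pass-through
#' metadata. All violations are reported together in one error.
#'
#' @param source Path to a JSON file, or a JSON string.
#' @return A [criterion_profile()].
#' @export
#' @examples
#' read_profile('{"cid_months": 12, "slow_response": 0, "rf_positive": 0,
#'   "flare_history": 1, "joint_damage": 0, "uveitis_history": 0,
#'   "spine_involvement": 0, "tmj_involvement": 0, "treatment_failure": 0,
#'   "prefer_continue": 1}')
read_profile <- function(source) {
  rec <- jsonlite::fromJSON(source, simplifyVector = TRUE)
  record_to_profile(rec, where = "profile")
}

#' Read a batch of patient profiles from CSV
#'
#' One profile per row; the header must name `cid_months` and the nine
#' criteria (canonical names or symbol aliases). Extra columns are routed
#' into each profile's `notes`. Malformed rows are reported individually,
#' by row number, in a single error; rows are never silently dropped.
#'
#' @param source Path to a CSV file (UTF-8, comma-separated, header
#'   required), or literal CSV text.
#' @return A list of [criterion_profile()] objects, one per row.
#' @export
read_batch <- function(source) {
  txt_input <- length(source) > 1 || grepl("[,\n]", source)
  df <- utils::read.csv(
    if (txt_input) textConnection(source) else source,
    colClasses = "character", check.names = FALSE, strip.white = TRUE
  )
  if (nrow(df) == 0) {
    warning("empty batch: no data rows")
    return(list())
  }
  results <- vector("list", nrow(df))
  errors <- character(0)
  for (i in seq_len(nrow(df))) {
    rec <- as.list(df[i, , drop = FALSE])
    res <- tryCatch(
      record_to_profile(rec, where = sprintf("row %d", i)),
      jiawithdraw_validation_error = function(e) e
    )
    if (inherits(res, "condition")) {
      errors <- c(errors, res$problems)
    } else {
      results[[i]] <- res
    }
  }
  if (length(errors) > 0) stop(validation_error(errors))
  results
}

#' Build a prediction report for one patient
#'
#' Bundles the echo of the inputs, the unadjusted prediction, optionally
#' the weight-adjusted prediction, and the pie-chart fractions (withdraw
#' vs. continue) that the decision-support tool displays.
#'
#' @param profile A [criterion_profile()].
#' @param coeffs A [coefficient_set()].
#' @param ratings Optional named 0-100 ratings; when given, the report
#'   also carries the adjusted prediction and the weight set.
#' @param seed Optional seed to record in the report (for logged runs).
#' @return An object of class `prediction_report`.
#' @export
prediction_report <- function(profile, coeffs = default_coefficients(),
                              ratings = NULL, seed = NULL) {
  pred <- predict_withdrawal(profile, coeffs)
  report <- list(
    model_version = model_version(),
    coefficient_hash = coefficient_hash(coeffs),
    patient_id = profile$patient_id,
    inputs = c(list(cid_months = profile$cid_months), as.list(profile$flags),
               if (!is.null(profile$notes)) list(notes = profile$notes)),
    prediction = unclass(pred),
    pie = list(withdraw = pred$p_withdraw, continue = 1 - pred$p_withdraw),
    percent = list(
      withdraw = round_half_up(100 * pred$p_withdraw),
      continue = 100 - round_half_up(100 * pred$p_withdraw)
    )
  )
  if (!is.null(ratings)) {
    weights <- if (inherits(ratings, "weight_set")) ratings
               else normalize_ratings(ratings)
    adj <- predict_withdrawal(profile, apply_weights(coeffs, weights))
    report$adjustment <- list(
      ratings = as.list(weights$ratings),
      normalized = as.list(weights$normalized),
      percent = as.list(to_percent(weights)$percent),
      prediction = unclass(adj),
      pie = list(withdraw = adj$p_withdraw, continue = 1 - adj$p_withdraw)
    )
  }
  if (!is.null(seed)) report$seed <- seed
  structure(report, class = "prediction_report")
}

#' Serialize a prediction report to JSON
#'
#' Numeric fields are written at full precision; display-rounded percent
#' fields are included alongside. Reports without an adjustment omit the
#' adjusted block entirely rather than null-filling it.
#'
#' @param report A [prediction_report()] (or a list of them).
#' @param path Output path; if `NULL` the JSON text is returned.
#' @param pretty Pretty-print the JSON.
#' @return JSON text (invisibly when written to `path`).
#' @export
write_report <- function(report, path = NULL, pretty = TRUE) {
  body <- if (inherits(report, "prediction_report")) unclass(report)
          else lapply(report, unclass)
  body <- drop_nulls(body)
  txt <- jsonlite::toJSON(body, auto_unbox = TRUE, digits = I(17),
                          pretty = pretty, null = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

drop_nulls <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!vapply(x, is.null, logical(1))]
  lapply(x, drop_nulls)
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("<prediction_report>",
      if (!is.null(x$patient_id)) paste0(" patient ", x$patient_id), "\n",
      sep = "")
  cat(sprintf("  withdraw %g%% / continue %g%%\n",
              x$percent$withdraw, x$percent$continue))
  if (!is.null(x$adjustment)) {
    cat(sprintf("  adjusted: withdraw %.1f%%\n",
                100 * x$adjustment$prediction$p_withdraw))
  }
  invisible(x)
}
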