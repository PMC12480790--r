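#' @keywords internal
"_PACKAGE"

#' Canonical criterion names
#'
#' The nine dichotomous patient, disease, and treatment criteria of the
#' withdrawal decision model, in canonical order. Each has a short symbol
#' used in the clinical literature, accepted everywhere as an alias.
#'
#' @return Named character vector: canonical names, named by their symbol
#'   alias (`RS`, `RF`, `F`, `JD`, `U`, `S`, `TMJ`, `TF`, `PPcontinue`).
#' @export
#' @examples
#' criterion_names()
criterion_names <- function() {
  c(
    RS         = "slow_response",
    RF         = "rf_positive",
    F          = "flare_history",
    JD         = "joint_damage",
    U          = "uveitis_history",
    S          = "spine_involvement",
    TMJ        = "tmj_involvement",
    TF         = "treatment_failure",
    PPcontinue = "prefer_continue"
  )
}

# Human-readable labels for report/CLI output.
criterion_labels <- function() {
  c(
    slow_response     = "Response to biologic therapy (CID reached in 6-12 mo)",
    rf_positive       = "RF-positive JIA",
    flare_history     = "History of flares",
    joint_damage      = "History of joint damage",
    uveitis_history   = "History of uveitis",
    spine_involvement = "History of spine involvement",
    tmj_involvement   = "TMJ involvement",
    treatment_failure = "History of treatment failure with biologics",
    prefer_continue   = "Child/parents prefer to continue therapy"
  )
}

# Map symbol aliases (and case-insensitive canonical names) to canonical
# names; unknown names are returned as NA.
canonicalize_criterion <- function(x) {
  nm <- criterion_names()
  out <- unname(nm[match(x, names(nm))])
  canon <- match(tolower(x), nm)
  out[is.na(out)] <- nm[canon[is.na(out)]]
  out
}

# Supported time-in-CID domain (months): the range over which the model was
# elicited and the prototype slider operated.
CID_DOMAIN <- c(6, 24)

#' Construct and validate a patient profile
#'
#' A profile holds the inputs of the withdrawal decision model: time in
#' clinically inactive disease (CID, months) and nine dichotomous criteria
#' coded 0/1. Validation is all-at-once: every violation is reported in a
#' single error so batch data entry can be fixed in one pass.
#'
#' @param cid_months Time in CID in months; must lie in `[6, 24]`, the
#'   domain over which the model is defined (withdrawal is not considered
#'   before 6 months of CID).
#' @param slow_response 1 if CID was reached 6-12 months after starting the
#'   biologic, 0 if in under 6 months. Response times over 12 months are
#'   outside the model's support and rejected.
#' @param rf_positive 1 for rheumatoid-factor-positive JIA.
#' @param flare_history 1 if the child has flared before.
#' @param joint_damage 1 for a history of joint damage.
#' @param uveitis_history 1 for a history of uveitis.
#' @param spine_involvement 1 for a history of spine involvement.
#' @param tmj_involvement 1 for temporomandibular-joint involvement.
#' @param treatment_failure 1 for a history of treatment failure with
#'   biologics.
#' @param prefer_continue 1 if the child and/or parents prefer to continue
#'   therapy, 0 if they prefer withdrawal.
#' @param patient_id Optional identifier, echoed into reports.
#' @param notes Optional free-text metadata (never used in computation).
#'
#' @return An object of class `criterion_profile`.
#' @export
#' @examples
#' criterion_profile(cid_months = 12, flare_history = 1, prefer_continue = 1)
criterion_profile <- function(cid_months,
                              slow_response = 0,
                              rf_positive = 0,
                              flare_history = 0,
                              joint_damage = 0,
                              uveitis_history = 0,
                              spine_involvement = 0,
                              tmj_involvement = 0,
                              treatment_failure = 0,
                              prefer_continue = 0,
                              patient_id = NULL,
                              notes = NULL) {
  flags <- c(
    slow_response = slow_response, rf_positive = rf_positive,
    flare_history = flare_history, joint_damage = joint_damage,
    uveitis_history = uveitis_history, spine_involvement = spine_involvement,
    tmj_involvement = tmj_involvement, treatment_failure = treatment_failure,
    prefer_continue = prefer_continue
  )
  problems <- character(0)
  if (length(cid_months) != 1L || !is.numeric(cid_months) ||
      !is.finite(cid_months)) {
    problems <- c(problems, "cid_months must be a single finite number")
  } else if (cid_months < CID_DOMAIN[1] || cid_months > CID_DOMAIN[2]) {
    problems <- c(problems, sprintf(
      "cid_months = %g is outside the supported domain [%g, %g] months",
      cid_months, CID_DOMAIN[1], CID_DOMAIN[2]
    ))
  }
  bad <- vapply(flags, function(v) {
    length(v) != 1L || !is.numeric(v) || is.na(v) || !(v %in% c(0, 1))
  }, logical(1))
  if (any(bad)) {
    problems <- c(problems, sprintf(
      "criterion '%s' must be exactly 0 or 1", names(flags)[bad]
    ))
  }
  if (length(problems) > 0) {
    stop(validation_error(problems))
  }
  structure(
    list(
      cid_months = as.numeric(cid_months),
      flags = vapply(flags, as.numeric, numeric(1)),
      patient_id = patient_id,
      notes = notes
    ),
    class = "criterion_profile"
  )
}

# A condition carrying an itemized list of input violations.
validation_error <- function(problems, call = sys.call(-1)) {
  structure(
    class = c("jiawithdraw_validation_error", "error", "condition"),
    list(
      message = paste0(
        "invalid input (", length(problems), " problem",
        if (length(problems) > 1) "s" else "", "):\n",
        paste0("  - ", problems, collapse = "\n")
      ),
      problems = problems,
      call = call
    )
  )
}

config_error <- function(msg, call = sys.call(-1)) {
  structure(
    class = c("jiawithdraw_config_error", "error", "condition"),
    list(message = msg, call = call)
  )
}

#' @export
print.criterion_profile <- function(x, ...) {
  cat("<criterion_profile>",
      if (!is.null(x$patient_id)) paste0(" id: ", x$patient_id), "\n", sep = "")
  cat("  time in CID: ", x$cid_months, " months\n", sep = "")
  on <- names(x$flags)[x$flags == 1]
  cat("  criteria present: ",
      if (length(on)) paste(on, collapse = ", ") else "(none)", "\n", sep = "")
  invisible(x)
}
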