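#' Continuation utility of a patient profile
#'
#' Evaluates the stated-preference utility of continuing biologic therapy:
#' the intercept plus the sum of the criterion coefficients over the flags
#' that are present. Time in CID does not enter the utility; it drives the
#' baseline term (see [baseline_withdrawal()]).
#'
#' @param profile A [criterion_profile()].
#' @param coeffs A [coefficient_set()]; defaults to the published model.
#' @return The utility, a single number.
#' @export
#' @examples
#' p <- criterion_profile(cid_months = 12)
#' continuation_utility(p)                       # intercept only: -1.61
#' continuation_utility(
#'   criterion_profile(cid_months = 12, prefer_continue = 1)
#' )                                             # -1.61 + 1.85 = 0.24
continuation_utility <- function(profile, coeffs = default_coefficients()) {
  stopifnot(inherits(profile, "criterion_profile"),
            inherits(coeffs, "coefficient_set"))
  flags <- profile$flags
  if (!setequal(names(flags), names(coeffs$betas))) {
    stop(config_error(paste0(
      "coefficient names do not match profile criteria; offending: ",
      paste(c(setdiff(names(coeffs$betas), names(flags)),
              setdiff(names(flags), names(coeffs$betas))), collapse = ", ")
    )))
  }
  unname(coeffs$intercept + sum(coeffs$betas * flags[names(coeffs$betas)]))
}

#' Probability that therapy is continued, given the utility
#'
#' The inverse-logit transform `exp(u) / (1 + exp(u))` of the continuation
#' utility: the model's probability that a pediatric rheumatologist would
#' choose to continue biologic therapy for this profile.
#'
#' @param utility A finite utility value (vectorized).
#' @return Probabilities strictly in (0, 1).
#' @export
continuation_probability <- function(utility) {
  if (!is.numeric(utility) || any(!is.finite(utility))) {
    stop(validation_error("utility must be finite"))
  }
  stats::plogis(utility)
}

#' Baseline withdrawal probability from time in CID
#'
#' The time component of the withdrawal model:
#' `baseline_intercept + baseline_slope * log(cid_months)`. With the
#' published parameters the raw value exceeds 1 for CID durations beyond
#' about 20.6 months, so the value used as a probability is clamped to
#' `[0, 1]`; the raw value is returned alongside so the formula stays
#' inspectable.
#'
#' @param cid_months Time in CID in months, in `[6, 24]` (vectorized).
#' @param coeffs A [coefficient_set()].
#' @param check_domain Set to `FALSE` to evaluate the formula outside the
#'   supported range (diagnostics only; predictions always check).
#' @return A list with `raw`, `clamped`, and logical `was_clamped`.
#' @export
#' @examples
#' baseline_withdrawal(12)
baseline_withdrawal <- function(cid_months, coeffs = default_coefficients(),
                                check_domain = TRUE) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  if (!is.numeric(cid_months) || any(!is.finite(cid_months)) ||
      any(cid_months <= 0)) {
    stop(validation_error("cid_months must be finite and positive"))
  }
  if (check_domain &&
      any(cid_months < CID_DOMAIN[1] | cid_months > CID_DOMAIN[2])) {
    stop(validation_error(sprintf(
      "cid_months outside the supported domain [%g, %g] months (the range over which the model was elicited)",
      CID_DOMAIN[1], CID_DOMAIN[2]
    )))
  }
  raw <- coeffs$baseline_intercept + coeffs$baseline_slope * log(cid_months)
  clamped <- pmin(1, pmax(0, raw))
  list(raw = raw, clamped = clamped, was_clamped = raw < 0 | raw > 1)
}

#' Predicted likelihood of biologic therapy withdrawal
#'
#' The full decision model: the baseline withdrawal probability at the
#' child's time in CID, multiplied by the probability that therapy would
#' *not* be continued given the nine criteria,
#' `p_withdraw = baseline * (1 - plogis(utility))`.
#'
#' @param profile A [criterion_profile()].
#' @param coeffs A [coefficient_set()].
#' @return An object of class `withdrawal_prediction` with fields
#'   `utility_continue`, `p_continue_given_profile`, `baseline_raw`,
#'   `baseline_clamped`, `p_withdraw`, and `clamped` (whether the baseline
#'   fell outside `[0, 1]`).
#' @export
#' @examples
#' predict_withdrawal(criterion_profile(cid_months = 12))
predict_withdrawal <- function(profile, coeffs = default_coefficients()) {
  u <- continuation_utility(profile, coeffs)
  p_cont <- continuation_probability(u)
  base <- baseline_withdrawal(profile$cid_months, coeffs)
  structure(
    list(
      utility_continue = u,
      p_continue_given_profile = p_cont,
      baseline_raw = base$raw,
      baseline_clamped = base$clamped,
      p_withdraw = base$clamped * (1 - p_cont),
      clamped = base$was_clamped
    ),
    class = "withdrawal_prediction"
  )
}

#' @export
print.withdrawal_prediction <- function(x, ...) {
  cat("<withdrawal_prediction>\n")
  cat(sprintf("  likelihood of withdrawal: %.1f%%%s\n",
              100 * x$p_withdraw,
              if (x$clamped) "  (baseline clamped to [0,1])" else ""))
  cat(sprintf("  continuation utility: %.4f  (P[continue | profile] = %.4f)\n",
              x$utility_continue, x$p_continue_given_profile))
  cat(sprintf("  time baseline: raw %.4f, used %.4f\n",
              x$baseline_raw, x$baseline_clamped))
  invisible(x)
}
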