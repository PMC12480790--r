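#' Construct a weight set from 0-100 ratings
#'
#' Ratings are positions on the prototype's 0 ("not important") to 100
#' ("very important") numerical rating scale, one per criterion. They are
#' normalized to fractions summing to 1; zero ratings stay exactly zero.
#'
#' @param ratings Named numeric vector (or list) of ratings in `[0, 100]`,
#'   one per criterion (symbol aliases accepted).
#' @return An object of class `weight_set` with fields `ratings` and
#'   `normalized`, both named in canonical criterion order.
#' @export
#' @examples
#' normalize_ratings(c(
#'   slow_response = 30, rf_positive = 31, flare_history = 74,
#'   joint_damage = 47, uveitis_history = 69, spine_involvement = 41,
#'   tmj_involvement = 19, treatment_failure = 59, prefer_continue = 100
#' ))
normalize_ratings <- function(ratings) {
  canonical <- unname(criterion_names())
  ratings <- unlist(ratings)
  if (is.null(names(ratings))) {
    stop(validation_error("ratings must be named by criterion"))
  }
  mapped <- canonicalize_criterion(names(ratings))
  problems <- character(0)
  if (anyNA(mapped)) {
    problems <- c(problems, paste0(
      "unknown criterion name(s): ",
      paste(names(ratings)[is.na(mapped)], collapse = ", ")
    ))
  } else {
    if (anyDuplicated(mapped)) {
      problems <- c(problems, "duplicate criterion names in ratings")
    }
    missing <- setdiff(canonical, mapped)
    if (length(missing) > 0) {
      problems <- c(problems, paste0(
        "ratings missing for: ", paste(missing, collapse = ", ")
      ))
    }
  }
  if (!is.numeric(ratings) || anyNA(ratings)) {
    problems <- c(problems, "all ratings must be numbers")
  } else if (any(ratings < 0 | ratings > 100)) {
    problems <- c(problems, sprintf(
      "rating for '%s' is outside [0, 100]",
      names(ratings)[ratings < 0 | ratings > 100]
    ))
  }
  if (length(problems) > 0) stop(validation_error(problems))
  ratings <- stats::setNames(as.numeric(ratings), mapped)[canonical]
  total <- sum(ratings)
  if (total == 0) {
    stop(validation_error(
      "all ratings are zero; at least one criterion must have weight"
    ))
  }
  structure(
    list(ratings = ratings, normalized = ratings / total),
    class = "weight_set"
  )
}

#' Relative importance of the criteria implied by the model
#'
#' Each criterion's share of the total decision weight is its coefficient
#' divided by the sum of all nine coefficients. Ratings are scaled so the
#' most important criterion sits at 100 on the 0-100 scale; any positive
#' scaling yields the same normalized weights and hence identical
#' predictions downstream.
#'
#' @param coeffs A [coefficient_set()]; all betas must be non-negative
#'   (relative importance is undefined for sign-mixed coefficients).
#' @return A `weight_set`.
#' @export
#' @examples
#' w <- derive_relative_importance()
#' to_percent(w)$percent   # the published importance list
derive_relative_importance <- function(coeffs = default_coefficients()) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  if (any(coeffs$betas < 0)) {
    stop(config_error(paste0(
      "relative importance is undefined when coefficients have mixed signs; negative: ",
      paste(names(coeffs$betas)[coeffs$betas < 0], collapse = ", ")
    )))
  }
  if (sum(coeffs$betas) <= 0) {
    stop(config_error("sum of betas must be positive"))
  }
  ratings <- coeffs$betas / max(coeffs$betas) * 100
  structure(
    list(ratings = ratings, normalized = coeffs$betas / sum(coeffs$betas)),
    class = "weight_set"
  )
}

# round half up, elementwise: 0.5 always rounds away from zero toward +Inf
round_half_up <- function(x) floor(x + 0.5)

#' Display weights as integer percentages
#'
#' Rounds each normalized weight to an integer percent with half-up
#' rounding (the display convention of the published importance list).
#' Because each entry is rounded independently, the integers need not sum
#' to exactly 100 (the default model's round to 101).
#'
#' @param weights A `weight_set`.
#' @return A list with `percent` (named integer vector) and `raw` (the
#'   unrounded percentages).
#' @export
to_percent <- function(weights) {
  stopifnot(inherits(weights, "weight_set"))
  raw <- 100 * weights$normalized
  list(percent = stats::setNames(as.integer(round_half_up(raw)), names(raw)),
       raw = raw)
}

#' Map adjusted weights back into model coefficients
#'
#' Rescales the criterion coefficients to the user's normalized weights
#' while conserving the total coefficient mass:
#' `beta'_k = normalized_k * sum(beta)`. The intercept and the time
#' baseline are left untouched, so applying the model's own derived
#' weights reproduces the original coefficients exactly and the utility
#' scale stays comparable across adjustments.
#'
#' @param coeffs A [coefficient_set()].
#' @param weights A `weight_set` (from [normalize_ratings()] or
#'   [derive_relative_importance()]).
#' @return A new [coefficient_set()] with rescaled betas.
#' @export
apply_weights <- function(coeffs, weights) {
  stopifnot(inherits(coeffs, "coefficient_set"),
            inherits(weights, "weight_set"))
  total <- sum(coeffs$betas)
  new_betas <- weights$normalized[names(coeffs$betas)] * total
  out <- coeffs
  out$betas <- new_betas
  out
}

#' Predict withdrawal under user-adjusted criterion weights
#'
#' Composes [normalize_ratings()], [apply_weights()], and
#' [predict_withdrawal()]: the 0-100 ratings are normalized, the
#' coefficients rescaled to match, and the likelihood of withdrawal
#' recomputed. At the model's default ratings the result is identical to
#' the unadjusted prediction.
#'
#' @param profile A [criterion_profile()].
#' @param coeffs A [coefficient_set()].
#' @param ratings Named ratings in `[0, 100]`, or an existing `weight_set`.
#' @return A `withdrawal_prediction` under the adjusted model.
#' @export
predict_with_adjustment <- function(profile, coeffs = default_coefficients(),
                                    ratings) {
  weights <- if (inherits(ratings, "weight_set")) ratings
             else normalize_ratings(ratings)
  predict_withdrawal(profile, apply_weights(coeffs, weights))
}

#' @export
print.weight_set <- function(x, ...) {
  pct <- to_percent(x)
  cat("<weight_set>\n")
  for (k in names(x$ratings)) {
    cat(sprintf("  %-18s rating %6.2f  weight %.4f  (%d%%)\n",
                k, x$ratings[[k]], x$normalized[[k]], pct$percent[[k]]))
  }
  invisible(x)
}
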