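#' Generate random patient profiles
#'
#' Draws synthetic patient profiles for vignette simulation: each criterion
#' flag is an independent Bernoulli draw at its stated prevalence, and time
#' in CID is uniform on `cid_range`. The default prevalence of 0.5 for every
#' criterion gives a balanced design carrying maximal information per
#' profile for coefficient recovery; clinically realistic prevalences can be
#' supplied per criterion instead.
#'
#' @param n Number of profiles.
#' @param prevalence Named vector of per-criterion prevalences in `[0, 1]`
#'   (symbol aliases accepted); a single unnamed value applies to all nine.
#' @param cid_range Interval for time in CID, within `[6, 24]` months.
#' @param seed Integer seed; identical seeds give identical profiles.
#' @return A data frame with `cid_months` and one 0/1 column per criterion.
#' @export
#' @examples
#' generate_profiles(5, seed = 1)
generate_profiles <- function(n, prevalence = 0.5, cid_range = c(6, 24),
                              seed = NULL) {
  canonical <- unname(criterion_names())
  if (length(prevalence) == 1 && is.null(names(prevalence))) {
    prevalence <- stats::setNames(rep(prevalence, 9), canonical)
  } else {
    mapped <- canonicalize_criterion(names(prevalence))
    if (anyNA(mapped)) {
      stop(validation_error(paste0(
        "unknown criterion in prevalence: ",
        paste(names(prevalence)[is.na(mapped)], collapse = ", ")
      )))
    }
    full <- stats::setNames(rep(0.5, 9), canonical)
    full[mapped] <- prevalence
    prevalence <- full
  }
  if (any(prevalence < 0 | prevalence > 1)) {
    stop(validation_error("prevalences must lie in [0, 1]"))
  }
  if (length(cid_range) != 2 || cid_range[1] > cid_range[2] ||
      cid_range[1] < CID_DOMAIN[1] || cid_range[2] > CID_DOMAIN[2]) {
    stop(validation_error(sprintf(
      "cid_range must be an interval within [%g, %g]",
      CID_DOMAIN[1], CID_DOMAIN[2]
    )))
  }
  if (!is.null(seed)) set.seed(seed)
  out <- data.frame(cid_months = stats::runif(n, cid_range[1], cid_range[2]))
  for (k in canonical) {
    out[[k]] <- stats::rbinom(n, 1, prevalence[[k]])
  }
  out
}

#' Full-factorial vignette profiles
#'
#' All `2^9 = 512` combinations of the nine criterion flags at a fixed time
#' in CID — the maximally informative design for recovering the choice
#' model's coefficients.
#'
#' @param cid_months Time in CID shared by all vignettes.
#' @return A 512-row data frame with `cid_months` and the nine flags.
#' @export
full_factorial_profiles <- function(cid_months = 12) {
  canonical <- unname(criterion_names())
  grid <- expand.grid(stats::setNames(rep(list(c(0, 1)), 9), canonical),
                      KEEP.OUT.ATTRS = FALSE)
  cbind(data.frame(cid_months = cid_months), grid)
}

#' Define a vignette-study design
#'
#' A design is a set of vignette profiles, each shown to `raters`
#' independent raters, plus the seed that drives choice simulation.
#' When coefficient recovery is intended the flag columns must have full
#' column rank (the full factorial always does).
#'
#' @param profiles Data frame of profiles (`cid_months` + nine flag
#'   columns), e.g. from [full_factorial_profiles()] or
#'   [generate_profiles()].
#' @param raters Raters per vignette.
#' @param seed Integer seed for choice simulation.
#' @param require_full_rank Check that the flag design matrix has full
#'   column rank.
#' @return An object of class `vignette_design`.
#' @export
vignette_design <- function(profiles, raters = 50, seed = 1,
                            require_full_rank = TRUE) {
  canonical <- unname(criterion_names())
  missing <- setdiff(c("cid_months", canonical), names(profiles))
  if (length(missing) > 0) {
    stop(validation_error(paste0(
      "profiles are missing columns: ", paste(missing, collapse = ", ")
    )))
  }
  if (raters < 1) stop(validation_error("raters must be >= 1"))
  X <- cbind(1, as.matrix(profiles[canonical]))
  if (require_full_rank && qr(X)$rank < ncol(X)) {
    stop(config_error(paste0(
      "design matrix is rank-deficient over the nine criteria; ",
      "coefficient recovery needs a richer set of vignettes"
    )))
  }
  structure(
    list(profiles = profiles, raters = as.integer(raters),
         seed = as.integer(seed)),
    class = "vignette_design"
  )
}

#' Simulate vignette-study choices
#'
#' For every (vignette, rater) pair the rater chooses to continue biologic
#' therapy with probability `plogis(U_continue(profile))` under the given
#' coefficients, and to withdraw otherwise — the data-generating process
#' the stated-preference model assumes.
#'
#' @param design A [vignette_design()].
#' @param coeffs A [coefficient_set()].
#' @return A `choice_dataset`: a data frame with one row per
#'   (vignette, rater) carrying the profile columns, `vignette`, `rater`,
#'   `continue` (0/1), and `choice` ("continue"/"withdraw").
#' @export
#' @examples
#' d <- vignette_design(full_factorial_profiles(), raters = 2, seed = 7)
#' head(simulate_choices(d))
simulate_choices <- function(design, coeffs = default_coefficients()) {
  stopifnot(inherits(design, "vignette_design"),
            inherits(coeffs, "coefficient_set"))
  canonical <- unname(criterion_names())
  profiles <- design$profiles
  n_v <- nrow(profiles)
  u <- coeffs$intercept +
    as.matrix(profiles[canonical]) %*% coeffs$betas[canonical]
  p_cont <- stats::plogis(as.numeric(u))
  idx <- rep(seq_len(n_v), each = design$raters)
  set.seed(design$seed)
  continue <- stats::rbinom(length(idx), 1, p_cont[idx])
  out <- profiles[idx, , drop = FALSE]
  rownames(out) <- NULL
  out$vignette <- idx
  out$rater <- rep(seq_len(design$raters), times = n_v)
  out$continue <- continue
  out$choice <- ifelse(continue == 1, "continue", "withdraw")
  class(out) <- c("choice_dataset", "data.frame")
  out
}

#' Refit the choice model to vignette data
#'
#' Maximum-likelihood logistic regression of the continue/withdraw choice
#' on the nine criterion flags — the estimation step of the vignette study.
#' The intercept and betas are estimated; the time-baseline parameters,
#' which are fit separately from aggregate withdrawal fractions (see
#' [fit_time_baseline()]), are copied from `baseline_from`.
#'
#' @param data A `choice_dataset` (or data frame with the nine flag columns
#'   and a 0/1 `continue` column).
#' @param baseline_from Coefficient set supplying the time-baseline
#'   parameters of the result.
#' @return A [coefficient_set()] with the fitted intercept and betas. The
#'   attribute `"fit"` carries `log_likelihood`, `iterations`, `converged`,
#'   and per-coefficient standard errors.
#' @export
fit_choice_model <- function(data, baseline_from = default_coefficients()) {
  canonical <- unname(criterion_names())
  missing <- setdiff(c(canonical, "continue"), names(data))
  if (length(missing) > 0) {
    stop(validation_error(paste0(
      "choice data are missing columns: ", paste(missing, collapse = ", ")
    )))
  }
  y <- data$continue
  if (length(unique(y)) < 2) {
    stop(config_error(
      "complete separation: every rater made the same choice; the logit likelihood has no maximum"
    ))
  }
  X <- cbind(1, as.matrix(data[canonical]))
  if (qr(X)$rank < ncol(X)) {
    stop(config_error(
      "singular design: the criterion columns are collinear; coefficients are not identifiable"
    ))
  }
  fml <- stats::as.formula(paste("continue ~", paste(canonical, collapse = " + ")))
  fit <- stats::glm(fml, family = stats::binomial(), data = data)
  if (!fit$converged) {
    stop(config_error("logit estimation did not converge"))
  }
  est <- stats::coef(fit)
  out <- coefficient_set(
    intercept = unname(est[["(Intercept)"]]),
    betas = est[canonical],
    baseline_intercept = baseline_from$baseline_intercept,
    baseline_slope = baseline_from$baseline_slope
  )
  attr(out, "fit") <- list(
    log_likelihood = as.numeric(stats::logLik(fit)),
    iterations = fit$iter,
    converged = fit$converged,
    se = summary(fit)$coefficients[, "Std. Error"]
  )
  out
}

#' Fit the log-time baseline to withdrawal fractions
#'
#' Least-squares fit of `fraction = a + b * log(months)` — the functional
#' form of the baseline withdrawal probability in time since CID. Given
#' fractions generated exactly by the model, the published parameters are
#' recovered to numerical precision.
#'
#' @param withdraw_fractions Named numeric vector (names = months) or a
#'   data frame with columns `months` and `fraction`.
#' @return Named numeric vector `c(intercept, slope)`.
#' @export
#' @examples
#' m <- c(6, 9, 12, 18, 24)
#' f <- -1.2861 + 0.7557 * log(m)
#' fit_time_baseline(stats::setNames(f, m))
fit_time_baseline <- function(withdraw_fractions) {
  if (is.data.frame(withdraw_fractions)) {
    months <- withdraw_fractions$months
    fraction <- withdraw_fractions$fraction
  } else {
    months <- as.numeric(names(withdraw_fractions))
    fraction <- as.numeric(withdraw_fractions)
  }
  if (anyNA(months) || any(months <= 0)) {
    stop(validation_error("months must be positive numbers"))
  }
  if (length(unique(months)) < 2) {
    stop(validation_error(
      "at least 2 distinct time points are needed to fit intercept and slope"
    ))
  }
  fit <- stats::lm(fraction ~ log(months))
  c(intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]))
}

#' Simulate-and-recover validation of the choice model
#'
#' Runs the model's own validation loop: simulate choices from a
#' coefficient set under a design, refit by maximum likelihood, and report
#' true versus estimated coefficients with absolute errors. Also verifies
#' the time baseline by noise-free recovery from model-generated fractions.
#'
#' @param coeffs True coefficients to simulate from.
#' @param design A [vignette_design()]; default full factorial at 12
#'   months, 50 raters per vignette.
#' @param seed Seed (overrides the design's seed when given).
#' @return A list with `table` (criterion, true, estimated, abs_error),
#'   `max_abs_error`, `baseline` (fitted intercept/slope and errors), and
#'   the fit diagnostics.
#' @export
simulate_recover <- function(coeffs = default_coefficients(),
                             design = NULL, seed = NULL) {
  if (is.null(design)) {
    design <- vignette_design(full_factorial_profiles(), raters = 50,
                              seed = if (is.null(seed)) 1L else seed)
  } else if (!is.null(seed)) {
    design$seed <- as.integer(seed)
  }
  data <- simulate_choices(design, coeffs)
  est <- fit_choice_model(data, baseline_from = coeffs)
  true_v <- c(intercept = coeffs$intercept, coeffs$betas)
  est_v <- c(intercept = est$intercept, est$betas)
  table <- data.frame(
    term = names(true_v),
    true = unname(true_v),
    estimated = unname(est_v),
    abs_error = unname(abs(true_v - est_v))
  )
  months <- c(6, 9, 12, 18, 24)
  frac <- coeffs$baseline_intercept + coeffs$baseline_slope * log(months)
  base_fit <- fit_time_baseline(stats::setNames(frac, months))
  list(
    table = table,
    max_abs_error = max(table$abs_error[table$term != "intercept"]),
    baseline = list(
      true = c(intercept = coeffs$baseline_intercept,
               slope = coeffs$baseline_slope),
      estimated = base_fit,
      abs_error = abs(base_fit - c(coeffs$baseline_intercept,
                                   coeffs$baseline_slope))
    ),
    fit = attr(est, "fit"),
    seed = design$seed,
    n_obs = nrow(data)
  )
}
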