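# Independent brute-force evaluation of the decision model, written as a
# straight transcription of the published formulas (term-by-term, its own
# constants, no package code). Used to cross-check predict_withdrawal.
oracle_p_withdraw <- function(cid_months, f) {
  u <- -1.61 +
    0.55 * f[["slow_response"]] +
    0.57 * f[["rf_positive"]] +
    1.36 * f[["flare_history"]] +
    0.87 * f[["joint_damage"]] +
    1.28 * f[["uveitis_history"]] +
    0.75 * f[["spine_involvement"]] +
    0.35 * f[["tmj_involvement"]] +
    1.09 * f[["treatment_failure"]] +
    1.85 * f[["prefer_continue"]]
  p_cont <- exp(u) / (1 + exp(u))
  base <- -1.2861 + 0.7557 * log(cid_months)
  if (base < 0) base <- 0
  if (base > 1) base <- 1
  base * (1 - p_cont)
}

# All 2^9 flag combinations as a matrix with canonical column names.
all_flag_combinations <- function() {
  nm <- unname(criterion_names())
  m <- as.matrix(expand.grid(rep(list(c(0, 1)), 9)))
  colnames(m) <- nm
  m
}

# Random valid profile as a named flag vector + cid time.
random_profile_inputs <- function() {
  nm <- unname(criterion_names())
  list(
    cid_months = stats::runif(1, 6, 24),
    flags = stats::setNames(stats::rbinom(9, 1, 0.5), nm)
  )
}

profile_from_inputs <- function(inp) {
  do.call(criterion_profile,
          c(list(cid_months = inp$cid_months), as.list(inp$flags)))
}

default_betas_oracle <- c(
  slow_response = 0.55, rf_positive = 0.57, flare_history = 1.36,
  joint_damage = 0.87, uveitis_history = 1.28, spine_involvement = 0.75,
  tmj_involvement = 0.35, treatment_failure = 1.09, prefer_continue = 1.85
)
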