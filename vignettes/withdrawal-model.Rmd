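---
title: "The biologic-withdrawal decision model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The biologic-withdrawal decision model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jiawithdraw)
```

## The decision problem

For a child with nonsystemic juvenile idiopathic arthritis (JIA) in
clinically inactive disease (CID) on a biologic, the clinician must weigh
withdrawing therapy (avoiding adverse events and cost, at the price of a
substantial flare risk) against continuing. The model implemented here does
not predict flares from outcome data; it predicts *peer behavior* — the
likelihood that pediatric rheumatologists, as a group, would withdraw
therapy for a given patient — from preferences stated in a clinical
vignette study.

## Model structure and assumptions

Two components multiply:

1. **A continuation utility.** Nine dichotomous criteria enter a linear
   logit utility `U = intercept + Σ βk·xk`. All nine coefficients are
   positive: every criterion, when present, argues for continuing. The
   probability of a "continue" choice is `plogis(U)`. Time in CID does not
   enter this utility.
2. **A time baseline.** The group's baseline inclination to withdraw grows
   logarithmically in time since CID: `b(t) = a + c·ln(t)` with default
   `a = -1.2861`, `c = 0.7557` and `t` in months.

The predicted withdrawal likelihood is `P = clamp(b(t), 0, 1) × (1 - plogis(U))`.
The multiplicative composition assumes the time effect and the profile
effect separate — the two components were elicited and are fitted
separately (see "Two-stage estimation" below).

### Clamping

With the default parameters `b(t)` crosses 1 at `t = exp((1 - a)/c) ≈ 20.6`
months and crosses 0 at `≈ 5.48` months. A displayed likelihood must be a
probability, so the baseline is clamped to `[0, 1]` before the product; the
raw value and a clamp flag are kept on every prediction so the unclamped
formula stays inspectable. Predictions therefore saturate in time beyond
~20.6 months.

### Domain

`cid_months` is restricted to `[6, 24]` — the range over which preferences
were elicited (withdrawal is not considered under 6 months of CID, and the
elicitation instrument capped at 24). Out-of-range values raise errors
rather than extrapolate; `baseline_withdrawal(..., check_domain = FALSE)`
exists solely for diagnostics such as locating the zero crossing.

### Coding decisions

* `slow_response` is two-level as elicited: 0 = CID within 6 months of
  starting the biologic, 1 = within 6–12 months. Response times over 12
  months have no defined coding in the utility and are rejected as outside
  model support rather than silently mapped to either level.
* `prefer_continue` codes 1 = family prefers to continue (the reference,
  0, is a preference to withdraw).
* Flags are strict 0/1 with no imputation: in the elicitation instrument
  every criterion was mandatory, so a missing criterion is an input error.
  Validation is all-at-once — every violation in a record (or every bad row
  in a CSV batch) is reported in a single error, which suits batch clinical
  data entry.

## Relative importance and weight adjustment

A criterion's relative importance is `βk / Σβ`, shown as an integer percent
with half-up rounding (the convention that reproduces the published display
list; independently rounded entries need not sum to 100 — the defaults sum
to 101). Default rating positions on the 0–100 scale are `βk / max(β) × 100`,
anchoring the most important criterion at 100; any positive rescaling of
ratings yields identical normalized weights and identical predictions, so
this anchor is purely presentational.

How adjusted ratings map back into coefficients is a genuine design choice:
the source material specifies the adjustment interface but not the
arithmetic behind it. The package rescales `β'k = wk · Σβ`, conserving the
total coefficient mass, and leaves the intercept and the time baseline
untouched. This mapping (i) reproduces the unadjusted model exactly at the
default weights, (ii) keeps the utility on a comparable scale across
adjustments, and (iii) makes "zero weight on a criterion" equivalent to
removing it from the model. Rescaling the intercept as well was considered
and rejected: it would change predictions even at default weights.

## Synthetic vignette data and parameter recovery

The generator emulates the data-generating process the stated-preference
model assumes: each (vignette, rater) pair draws "continue" with probability
`plogis(U(profile))`, independently across raters. Supported designs are the
512-profile full factorial (used for validation, since it is balanced and
maximally informative) and random profiles with per-criterion prevalences.
The default prevalence of 0.5 per criterion is the balanced choice that
maximizes information per profile for recovery; it is not a claim about
clinical prevalence, and realistic prevalences can be supplied per
criterion.

What passing recovery shows — and what it does not: refitting by maximum
likelihood (a standard binomial GLM) on data simulated from the model
checks the estimation machinery, identifiability of the design, and the
internal consistency of simulator and likelihood. It does not validate the
published coefficient values against real clinicians, the independence of
raters, or the absence of respondent heterogeneity (a mixed logit is out of
scope; the model carries group-average weights only).

At the validation problem size (512 vignettes × 50 raters = 25,600
choices), pre-computed Monte-Carlo standard errors of the recovered betas
are roughly 0.03–0.05, so the documented recovery tolerance of ±0.15 per
coefficient is about three standard errors. Bias shrinks with raters per
vignette, which the test suite checks at three sample sizes.

### Two-stage estimation

The choice logit (intercept + nine betas) and the time baseline are fitted
separately: the logit by maximum likelihood on individual choices, the
baseline by least squares of withdrawal fractions on `ln(months)`. This
mirrors the model's own multiplicative structure, in which the baseline
depends only on time. Fed fractions generated exactly by the model at
months {6, 9, 12, 18, 24}, the baseline fit returns the default parameters
to numerical precision.

### Numerical and degeneracy choices

* All randomness flows through explicit integer seeds; identical seeds give
  identical datasets, fits, and reports.
* Rank of the design over the nine flags is checked before simulation when
  recovery is intended; a rank-deficient design, complete separation (all
  choices identical), or collinear flag columns raise explicit estimation
  errors instead of silently diverging.
* The decomposition identity `p_withdraw = baseline_clamped × (1 - plogis(U))`
  is enforced to 1e−12, and predictions are cross-checked against an
  independently coded brute-force evaluation of the formulas over all 512
  flag combinations at three time points to 1e−10.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `intercept` | −1.61 | utility | continuation utility with no criteria present |
| `betas` (9) | 0.35–1.85 | utility | criterion effects on continuation |
| `baseline_intercept` | −1.2861 | probability | baseline withdrawal at `ln(t) = 0` |
| `baseline_slope` | 0.7557 | per ln(month) | growth of baseline withdrawal in log time |
| `cid_months` | — | months | time in CID, domain [6, 24] |
| ratings | derived | 0–100 scale | user-adjusted criterion importance |
| `raters` | 50 | count | raters per vignette in simulation |
| `prevalence` | 0.5 | fraction | per-criterion flag prevalence in random designs |

Alternative coefficient sets are supplied as JSON
(`read_coefficients()`); the packaged default reproduces the published
model exactly.

## Known limitations

* The model predicts the *stated* withdrawal behavior of a modest group of
  pediatric rheumatologists from two countries; its estimates carry wide
  confidence intervals, which is precisely why the weight-adjustment
  interface exists.
* Predictions saturate (baseline clamped at 1) beyond ≈ 20.6 months in CID,
  so profiles differ there only through the utility factor.
* No flare-risk prognosis, no respondent heterogeneity, no persistence of
  user weights across sessions.
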