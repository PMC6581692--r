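# Per-delivery outcome models, all vectorised over women. Mortality is a
# reduced-form logistic on the facility-capability variables (readiness,
# caesarean capability and performance) plus the woman's obstetric risk;
# the woman's wealth enters outcomes only through where she delivers.

#' Simulate caesarean delivery
#'
#' A caesarean can only happen at a caesarean-capable facility; there the
#' probability is `p_need` for women with a predicted caesarean need and
#' `p_background` otherwise.
#'
#' @param women Cohort tibble rows (needs `predicted_cs_need`).
#' @param facilities Matching facility rows (needs `cemonc_capable`),
#'   recycled if a single row.
#' @param params The `outcome_model` config block (or full config).
#' @param u Optional uniform draws (one per woman) for common-random-number
#'   pairing; defaults to fresh draws.
#' @return Logical vector.
#' @export
caesarean_delivered <- function(women, facilities, params, u = NULL) {
  params <- outcome_params(params)
  n <- nrow(women)
  capable <- rep_len(facilities$cemonc_capable, n)
  p <- ifelse(capable,
              ifelse(women$predicted_cs_need, params$caesarean$p_need,
                     params$caesarean$p_background), 0)
  u <- u %||% runif(n)
  u < p
}

#' Simulate neonatal death
#'
#' Bernoulli draw from a logistic risk:
#' `logit(p) = b0 + b_risky risky + b_mult multiple + b_ready readiness +
#' b_cemonc capable + b_cs caesarean`. With the default negative
#' coefficients on readiness, capability and caesarean, risk falls at
#' better-equipped facilities; the woman's wealth never enters directly.
#'
#' @param women Cohort rows (needs `risky_delivery`, `multiple_gestation`).
#' @param facilities Matching facility rows (needs `readiness_score`,
#'   `cemonc_capable`), recycled if a single row.
#' @param caesarean Logical vector: was a caesarean performed.
#' @param params The `outcome_model` config block (or full config).
#' @param u Optional uniform draws.
#' @return Logical vector.
#' @export
neonatal_death <- function(women, facilities, caesarean, params, u = NULL) {
  params <- outcome_params(params)
  mm <- params$mortality
  n <- nrow(women)
  lp <- mm$intercept +
    mm$risky_delivery * women$risky_delivery +
    mm$multiple_gestation * women$multiple_gestation +
    mm$readiness_score * rep_len(facilities$readiness_score, n) +
    mm$cemonc_capable * rep_len(facilities$cemonc_capable, n) +
    mm$caesarean * caesarean
  u <- u %||% runif(n)
  u < plogis(lp)
}

#' Out-of-pocket delivery cost
#'
#' Deterministic: the facility's delivery fee (only when it charges fees),
#' plus the non-fee direct cost for its type, plus round-trip transport at
#' the configured USD/km rate.
#'
#' @param facilities Facility rows (needs `ftype`, `charges_fees`).
#' @param distance_km One-way travel distance per woman.
#' @param params The `cost_model` config block (or full config).
#' @return Numeric USD vector.
#' @export
out_of_pocket_cost <- function(facilities, distance_km, params) {
  params <- cost_params(params)
  if (any(distance_km < 0)) abort("distance_km must be non-negative")
  n <- length(distance_km)
  ftype_chr <- rep_len(as.character(facilities$ftype), n)
  fees <- rep_len(facilities$charges_fees, n)
  unname(
    ifelse(fees, unlist(params$facility_fee_usd)[ftype_chr], 0) +
      unlist(params$nonfee_cost_usd)[ftype_chr] +
      params$transport_cost_usd_per_km * params$round_trip_factor * distance_km
  )
}

#' Catastrophic-expenditure flag
#'
#' An expense is catastrophic when it exceeds (strictly) the threshold
#' fraction of the woman's yearly expenditure — 10% by default, so a cost
#' of exactly 10% is not catastrophic.
#'
#' @param oop_cost Out-of-pocket cost in USD.
#' @param yearly_expenditure Yearly consumption expenditure in USD
#'   (positive).
#' @param threshold Fraction of yearly expenditure (default 0.10).
#' @return Logical vector.
#' @examples
#' is_catastrophic(13.70, 137) # exactly 10%: not catastrophic
#' is_catastrophic(19.59, 137)
#' @export
is_catastrophic <- function(oop_cost, yearly_expenditure, threshold = 0.10) {
  if (any(yearly_expenditure <= 0)) abort("yearly_expenditure must be positive")
  oop_cost > threshold * yearly_expenditure
}

outcome_params <- function(x) {
  if (!is.null(x$outcome_model)) x <- x$outcome_model
  if (is.null(x$mortality) || is.null(x$caesarean)) {
    abort("not an outcome_model block: needs 'mortality' and 'caesarean'")
  }
  x
}

cost_params <- function(x) {
  if (!is.null(x$cost_model)) x <- x$cost_model
  if (is.null(x$facility_fee_usd) || is.null(x$nonfee_cost_usd)) {
    abort("not a cost_model block: needs fee and non-fee cost tables")
  }
  x$round_trip_factor <- x$round_trip_factor %||% 2
  x
}
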