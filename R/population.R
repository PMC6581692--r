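# Synthetic cohort generator. Wealth, location and urbanicity are drawn
# jointly: locations come from a mixture of urban kernels and a rural
# background, and the wealth quintile follows a proportional-odds model on
# distance to the nearest urban centre, so that (with a positive gradient)
# the poorest women live farthest from the cities. All other covariates are
# independent draws from configured marginals.

urban_centre_matrix <- function(pop) {
  do.call(rbind, lapply(pop$urban_centres, function(u) c(u$lat, u$lon)))
}

# Truncated Poisson on 0..max via inverse CDF (vectorised).
rpois_trunc <- function(n, mean, max) {
  probs <- stats::dpois(0:max, mean)
  probs <- probs / sum(probs)
  sample.int(max + 1L, n, replace = TRUE, prob = probs) - 1L
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

sample_locations <- function(pop, n, island = NULL) {
  bbox <- pop$bbox
  centres <- urban_centre_matrix(pop)
  weights <- vapply(pop$urban_centres, `[[`, 0, "weight")
  sds <- vapply(pop$urban_centres, `[[`, 0, "sd_deg")
  urban <- runif(n) < pop$urban_share
  lat <- runif(n, bbox$lat_min, bbox$lat_max)
  lon <- runif(n, bbox$lon_min, bbox$lon_max)
  if (any(urban)) {
    k <- sample.int(nrow(centres), sum(urban), replace = TRUE, prob = weights)
    lat[urban] <- rnorm(sum(urban), centres[k, 1], sds[k])
    lon[urban] <- rnorm(sum(urban), centres[k, 2], sds[k])
  }
  if (!is.null(island) && isTRUE(island$enabled) && island$population_share > 0) {
    on_island <- runif(n) < island$population_share
    m <- sum(on_island)
    if (m > 0) {
      lat[on_island] <- island$lat + runif(m, -island$radius_deg, island$radius_deg)
      lon[on_island] <- island$lon + runif(m, -island$radius_deg, island$radius_deg)
      urban[on_island] <- FALSE
    }
  }
  lat <- pmin(pmax(lat, bbox$lat_min), bbox$lat_max)
  lon <- pmin(pmax(lon, bbox$lon_min), bbox$lon_max)
  list(lat = lat, lon = lon, urban = urban)
}

# Proportional-odds wealth draw: cutpoints reproduce the configured
# marginals exactly when the gradient is zero; a positive gradient shifts
# mass toward the poorer quintiles as distance (centred at its cohort mean)
# grows.
sample_wealth_quintile <- function(dist_km, pop) {
  marg <- unlist(pop$wealth_quintile_marginals)
  cuts <- qlogis(pmin(cumsum(marg)[1:4], 1 - 1e-12))
  g <- pop$wealth_distance_gradient %||% 0
  shift <- g * (dist_km - mean(dist_km))
  cum <- vapply(cuts, function(ck) plogis(ck + shift), numeric(length(dist_km)))
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1)
  u <- runif(length(dist_km))
  as.integer(1L + rowSums(u > cum))
}

#' Draw yearly consumption expenditure by wealth quintile
#'
#' Gamma draws whose per-quintile means are the configured
#' `quintile_means`, rescaled so their marginal-weighted average equals the
#' configured national mean (137 USD by default). An infinite
#' `gamma_shape` gives degenerate draws at the quintile mean.
#'
#' @param quintile Integer vector of wealth quintiles (1 = poorest).
#' @param config Full `regiosim_config` (or a list with `population` and
#'   `mean_yearly_expenditure_usd`).
#' @return Positive numeric vector of USD amounts, drawn from the current
#'   RNG stream.
#' @export
sample_yearly_expenditure <- function(quintile, config) {
  if (any(!quintile %in% 1:5)) abort("quintile must lie in 1..5")
  pop <- config$population
  qm <- unlist(pop$expenditure$quintile_means)
  marg <- unlist(pop$wealth_quintile_marginals)
  qm <- qm * config$mean_yearly_expenditure_usd / sum(qm * marg)
  shape <- pop$expenditure$gamma_shape
  mu <- qm[quintile]
  if (is.infinite(shape)) return(mu)
  pmax(rgamma(length(quintile), shape = shape, scale = mu / shape), 1e-6)
}

#' Generate a synthetic cohort of pregnant women
#'
#' Draws `n` agents. Location, urbanicity and wealth are drawn jointly
#' (urban kernel mixture plus a distance-to-city wealth gradient); parity,
#' age, literacy, education, marital status, antenatal visits, multiple
#' gestation, risky delivery and predicted caesarean need are independent
#' draws from the configured marginals; yearly expenditure is gamma by
#' quintile.
#'
#' @param config Full `regiosim_config`.
#' @param n Number of women (positive integer).
#' @param seed Integer seed; fixed seed reproduces the cohort exactly.
#' @return A tibble with one row per woman (see [write_cohort()] for the
#'   column layout).
#' @examples
#' cfg <- default_config()
#' cohort <- sample_cohort(cfg, n = 100, seed = 1)
#' dplyr::count(cohort, wealth_quintile)
#' @export
sample_cohort <- function(config, n, seed) {
  if (n < 1) abort("n must be >= 1")
  pop <- config$population
  withr::with_seed(seed, {
    loc <- sample_locations(pop, n, island = config$network$island)
    centres <- urban_centre_matrix(pop)
    d_urban <- haversine_cross_km(cbind(loc$lat, loc$lon), centres)
    dist_km <- do.call(pmin, as.data.frame(d_urban))
    quintile <- sample_wealth_quintile(dist_km, pop)
    cv <- pop$covariates
    tibble(
      id = seq_len(n),
      lat = loc$lat,
      lon = loc$lon,
      urban = loc$urban,
      wealth_quintile = quintile,
      literacy = runif(n) < cv$literacy_prob,
      education = sample.int(4L, n, replace = TRUE, prob = unlist(cv$education_probs)) - 1L,
      parity = rpois_trunc(n, cv$parity_mean, 10L),
      age_years = rnorm_trunc(n, cv$age_mean, cv$age_sd, cv$age_min, cv$age_max),
      married = runif(n) < cv$married_prob,
      anc_visits = rpois_trunc(n, cv$anc_visits_mean, 12L),
      multiple_gestation = runif(n) < cv$multiple_gestation_prob,
      risky_delivery = runif(n) < cv$risky_delivery_prob,
      predicted_cs_need = runif(n) < cv$predicted_cs_need_prob,
      yearly_expenditure_usd = sample_yearly_expenditure(quintile, config),
      dist_to_urban_km = dist_km
    )
  })
}
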