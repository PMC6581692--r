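#' Basic obstetric readiness score
#'
#' The unweighted mean of the binary readiness-item indicators (equipment
#' and resources required for obstetric care), in `[0, 1]`.
#'
#' @param items Logical (or 0/1) vector of item availabilities.
#' @return A single number in `[0, 1]`.
#' @examples
#' readiness_score(c(TRUE, TRUE, FALSE, TRUE))
#' @export
readiness_score <- function(items) {
  if (length(items) == 0) abort("readiness items must be a non-empty vector")
  if (anyNA(items)) abort("readiness items must not contain NA")
  mean(as.logical(items))
}

#' Generate a synthetic facility registry
#'
#' Draws `n_facilities` delivery facilities with a configurable type mix
#' (dominated by health centres by default), locations concentrated near
#' the urban centres for the hospital tiers, readiness positively
#' correlated with urban proximity, caesarean capability tied to type
#' probabilities (all central and district hospitals capable by default),
#' fees concentrated in private and NGO facilities, and a recent count of
#' basic emergency obstetric and neonatal care signal functions.
#'
#' @param config Full `regiosim_config`.
#' @param n_facilities Number of facilities (default from config).
#' @param seed Integer seed.
#' @return Facility tibble (see [write_facilities()] for columns, plus
#'   `item_*` readiness indicators and `dist_to_urban_km`).
#' @examples
#' reg <- generate_synthetic_facilities(default_config(), n_facilities = 50, seed = 1)
#' dplyr::count(reg, ftype)
#' @export
generate_synthetic_facilities <- function(config, n_facilities = NULL, seed = 1) {
  fac <- config$facilities
  n <- as.integer(n_facilities %||% fac$n_facilities)
  if (n < 1) abort("n_facilities must be >= 1")
  pop <- config$population
  withr::with_seed(seed, {
    type_probs <- unlist(fac$type_probs)[FACILITY_TYPES]
    # guarantee at least one facility of each configured type when there
    # is room; types with zero probability are never drawn
    must <- FACILITY_TYPES[type_probs > 0]
    ftype <- if (n >= length(must)) {
      extra <- sample(FACILITY_TYPES, n - length(must), replace = TRUE, prob = type_probs)
      sample(c(must, extra))
    } else {
      sample(FACILITY_TYPES, n, replace = TRUE, prob = type_probs)
    }
    ftype <- factor(ftype, levels = FACILITY_TYPES)

    # hospitals gravitate to cities; smaller facilities follow the population
    urban_pull <- ifelse(ftype %in% c("central_hospital", "other_hospital"), 0.95,
                  ifelse(ftype == "district_hospital", 0.6, fac$urban_share))
    loc_pop <- pop
    loc <- sample_locations(loc_pop, n)
    centres <- urban_centre_matrix(pop)
    weights <- vapply(pop$urban_centres, `[[`, 0, "weight")
    sds <- vapply(pop$urban_centres, `[[`, 0, "sd_deg")
    to_urban <- runif(n) < urban_pull
    if (any(to_urban)) {
      k <- sample.int(nrow(centres), sum(to_urban), replace = TRUE, prob = weights)
      loc$lat[to_urban] <- rnorm(sum(to_urban), centres[k, 1], sds[k] * 1.5)
      loc$lon[to_urban] <- rnorm(sum(to_urban), centres[k, 2], sds[k] * 1.5)
    }
    lat <- pmin(pmax(loc$lat, pop$bbox$lat_min), pop$bbox$lat_max)
    lon <- pmin(pmax(loc$lon, pop$bbox$lon_min), pop$bbox$lon_max)
    d_urban <- do.call(pmin, as.data.frame(haversine_cross_km(cbind(lat, lon), centres)))

    base <- unlist(fac$readiness_base)[as.character(ftype)]
    lp <- base +
      fac$readiness_urban_gain * pmax(0, 1 - d_urban / fac$readiness_ref_distance_km) +
      rnorm(n, 0, fac$readiness_noise_sd)
    target <- plogis(lp)
    k_items <- fac$n_readiness_items
    items <- matrix(runif(n * k_items) < target, nrow = n)
    colnames(items) <- paste0("item_", seq_len(k_items))
    score <- rowMeans(items)

    mgmt_probs <- fac$management_probs
    management <- vapply(as.character(ftype), function(tp) {
      sample(MANAGEMENT_TYPES, 1, prob = unlist(mgmt_probs[[tp]]))
    }, "")
    charges_fees <- runif(n) < unlist(fac$fee_prob)[management]
    cemonc <- runif(n) < unlist(fac$cemonc_prob)[as.character(ftype)]
    bemonc <- rpois(n, unlist(fac$bemonc_mean)[as.character(ftype)])

    bind_cols(
      tibble(
        id = seq_len(n), lat = lat, lon = lon, ftype = ftype,
        management = unname(management), charges_fees = unname(charges_fees),
        readiness_score = score, cemonc_capable = unname(cemonc),
        bemonc_count_3mo = as.integer(bemonc), dist_to_urban_km = d_urban
      ),
      as_tibble(items)
    )
  })
}

qualifies <- function(registry, target) {
  switch(target,
    cemonc = registry$cemonc_capable,
    bemonc5 = registry$bemonc_count_3mo >= 5L,
    abort(sprintf("unknown upgrade target '%s'", target))
  )
}

#' Facilities eligible under a scenario's restriction
#'
#' `cemonc_only` keeps exactly the caesarean-capable facilities;
#' `bemonc5_only` keeps facilities reporting five or more basic emergency
#' obstetric and neonatal care signal functions in the preceding 3 months;
#' `none` (or `restrict_after_upgrade = FALSE`) keeps all.
#'
#' @param registry Facility tibble (upgrades, if any, already applied).
#' @param scenario A scenario spec list (see [load_config()]).
#' @return The eligible subset of `registry`; errors if empty.
#' @export
eligible_facilities <- function(registry, scenario) {
  scenario <- normalize_scenario(scenario)
  keep <- if (scenario$restriction == "none" || !scenario$restrict_after_upgrade) {
    rep(TRUE, nrow(registry))
  } else if (scenario$restriction == "cemonc_only") {
    registry$cemonc_capable
  } else {
    registry$bemonc_count_3mo >= 5L
  }
  out <- registry[keep, , drop = FALSE]
  if (!nrow(out)) {
    abort(sprintf("scenario '%s' leaves no eligible facility", scenario$name))
  }
  out
}

#' Greedy maximal-coverage upgrade selection
#'
#' Chooses `k` not-yet-qualifying facilities to upgrade so as to maximise
#' the number of women within `radius_km` of a qualifying facility. Women
#' already covered by a currently qualifying facility count as covered from
#' the start; each greedy step picks the candidate covering the most still
#' uncovered women, breaking ties by lowest facility id.
#'
#' @param registry Facility tibble.
#' @param population Cohort tibble (used only for locations).
#' @param target `"cemonc"` or `"bemonc5"`: the capability being added.
#' @param k Number of upgrades.
#' @param radius_km Coverage radius (straight-line km).
#' @param distance_fn Function(points_a, points_b) returning a cross-distance
#'   matrix in km; defaults to the haversine.
#' @return Integer vector of `k` facility ids, in selection order.
#' @export
select_upgrades <- function(registry, population, target, k, radius_km,
                            distance_fn = haversine_cross_km) {
  k <- as.integer(k)
  if (k == 0L) return(integer(0))
  qual <- qualifies(registry, target)
  candidates <- registry$id[!qual]
  if (k > length(candidates)) {
    abort(sprintf("k = %d exceeds the %d non-qualifying candidate facilities",
                  k, length(candidates)))
  }
  pts_w <- cbind(population$lat, population$lon)
  pts_f <- cbind(registry$lat, registry$lon)
  within <- distance_fn(pts_f, pts_w) <= radius_km # facilities x women
  covered <- if (any(qual)) colSums(within[qual, , drop = FALSE]) > 0 else
    rep(FALSE, nrow(population))
  cand_idx <- which(!qual)
  cand_idx <- cand_idx[order(registry$id[cand_idx])] # tie-break: lowest id first
  chosen <- integer(0)
  for (step in seq_len(k)) {
    gains <- colSums(t(within[cand_idx, , drop = FALSE]) & !covered)
    best <- cand_idx[which.max(gains)] # first maximum = lowest id
    chosen <- c(chosen, registry$id[best])
    covered <- covered | within[best, ]
    cand_idx <- setdiff(cand_idx, best)
  }
  chosen
}

#' Apply a policy scenario to a facility registry
#'
#' In order: (1) upgrade the maximal-coverage facilities to the target
#' capability (caesarean capability, or a basic emergency care volume of
#' five signal functions), raising their readiness to at least the median
#' readiness of already-qualifying facilities; (2) remove direct user fees
#' if requested; (3) set full obstetric readiness everywhere if requested;
#' (4) compute the eligible set (all facilities when the scenario upgrades
#' without restricting).
#'
#' @inheritParams select_upgrades
#' @param scenario Scenario spec list.
#' @param distance_fn Distance function for coverage siting.
#' @return A list with `registry` (modified tibble), `eligible_ids`
#'   (integer vector) and `upgraded_ids`.
#' @export
apply_scenario <- function(registry, scenario, population = NULL,
                           distance_fn = haversine_cross_km) {
  scenario <- normalize_scenario(scenario)
  upgraded <- integer(0)
  if (scenario$n_upgrades > 0L) {
    if (is.null(population)) {
      abort(sprintf("scenario '%s' upgrades facilities and needs a population for siting",
                    scenario$name))
    }
    upgraded <- select_upgrades(registry, population, scenario$upgrade_target,
                                scenario$n_upgrades, scenario$coverage_radius_km,
                                distance_fn)
    qual <- qualifies(registry, scenario$upgrade_target)
    floor_readiness <- if (any(qual)) median(registry$readiness_score[qual]) else
      max(registry$readiness_score)
    rows <- registry$id %in% upgraded
    if (scenario$upgrade_target == "cemonc") {
      registry$cemonc_capable[rows] <- TRUE
    } else {
      registry$bemonc_count_3mo[rows] <- pmax(registry$bemonc_count_3mo[rows], 5L)
    }
    registry$readiness_score[rows] <- pmax(registry$readiness_score[rows], floor_readiness)
  }
  if (scenario$remove_fees) registry$charges_fees <- FALSE
  if (scenario$full_readiness) registry$readiness_score <- 1
  eligible <- eligible_facilities(registry, scenario)
  list(registry = registry, eligible_ids = eligible$id, upgraded_ids = upgraded)
}

#' Compensatory and unrestricted scenario analyses
#'
#' The packaged scenario-analysis specs: the two upgrade scenarios with the
#' restriction lifted (women free to choose any facility), and the
#' compensatory policies layered on the strictest restriction — fee
#' removal, full obstetric readiness, and both.
#'
#' @return A list of scenario spec lists, appendable to
#'   `config$scenarios`.
#' @export
scenario_analyses <- function() {
  lapply(list(
    list(name = "scenario2_upgrade_no_restriction", restriction = "cemonc_only",
         n_upgrades = 20L, upgrade_target = "cemonc", restrict_after_upgrade = FALSE),
    list(name = "scenario4_upgrade_no_restriction", restriction = "bemonc5_only",
         n_upgrades = 30L, upgrade_target = "bemonc5", restrict_after_upgrade = FALSE),
    list(name = "scenario1_no_fees", restriction = "cemonc_only", remove_fees = TRUE),
    list(name = "scenario1_full_readiness", restriction = "cemonc_only", full_readiness = TRUE),
    list(name = "scenario1_no_fees_full_readiness", restriction = "cemonc_only",
         remove_fees = TRUE, full_readiness = TRUE)
  ), normalize_scenario)
}
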