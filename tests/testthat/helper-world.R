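# Shared fixtures, all built in code: a hand-laid grid road network with a
# disconnected island, tiny facility registries and cohorts, compact choice
# parameters without facility-type dummies, and a scaled-down configuration
# for pipeline tests.

# 3x3 grid of nodes spaced 0.1 deg around the origin, edges = straight-line
# distance * 1.2, plus a two-node island ~200 km east connected only to
# itself. Node ids 1..9 row-major from (lat 0, lon 0).
toy_network <- function(detour = 1.2) {
  grid <- expand.grid(row = 0:2, col = 0:2)
  nodes <- tibble::tibble(
    id = 1:9, lat = grid$row * 0.1, lon = grid$col * 0.1
  )
  pairs <- rbind(
    cbind(1:6, 4:9),                                # column step (id + 3)
    cbind(c(1, 4, 7, 2, 5, 8), c(2, 5, 8, 3, 6, 9)) # row step (id + 1)
  )
  gap <- regiosim::haversine_km(
    cbind(nodes$lat[pairs[, 1]], nodes$lon[pairs[, 1]]),
    cbind(nodes$lat[pairs[, 2]], nodes$lon[pairs[, 2]])
  )
  edges <- tibble::tibble(from = pairs[, 1], to = pairs[, 2], length_km = gap * detour)
  island <- tibble::tibble(id = 100:101, lat = c(0, 0.05), lon = c(2, 2))
  igap <- regiosim::haversine_km(c(0, 2), c(0.05, 2))
  build_network(
    dplyr::bind_rows(nodes, island),
    dplyr::bind_rows(edges, tibble::tibble(from = 100, to = 101, length_km = igap * detour))
  )
}

toy_facilities <- function(n = 3,
                           lat = rep(0, n), lon = seq(0, 0.2, length.out = n),
                           ftype = rep("health_centre", n),
                           charges_fees = rep(FALSE, n),
                           readiness = rep(0.5, n),
                           cemonc = rep(FALSE, n),
                           bemonc = rep(3L, n)) {
  tibble::tibble(
    id = seq_len(n), lat = lat, lon = lon,
    ftype = factor(ftype, levels = regiosim:::FACILITY_TYPES),
    management = rep("public", n), charges_fees = charges_fees,
    readiness_score = readiness, cemonc_capable = cemonc,
    bemonc_count_3mo = as.integer(bemonc)
  )
}

toy_cohort <- function(n = 5, lat = rep(0.05, n), lon = rep(0.05, n),
                       quintile = rep(3L, n), expenditure = rep(137, n),
                       risky = rep(FALSE, n), cs_need = rep(FALSE, n)) {
  tibble::tibble(
    id = seq_len(n), lat = lat, lon = lon, urban = FALSE,
    wealth_quintile = as.integer(quintile), literacy = TRUE, education = 1L,
    parity = 2L, age_years = 25, married = TRUE, anc_visits = 3L,
    multiple_gestation = FALSE, risky_delivery = risky,
    predicted_cs_need = cs_need, yearly_expenditure_usd = expenditure
  )
}

# Minimal 2-class parameters on distance/fees/readiness only.
toy_params <- function(bd1 = -0.1, bd2 = -0.05, bfee1 = -2, bfee2 = -0.4,
                       bread1 = 0.5, bread2 = 2, memb_intercept = 0,
                       se = 0, deterministic = FALSE) {
  choice_params(list(
    n_classes = 2,
    deterministic_choice = deterministic,
    membership = list(class2 = list(
      coef = list(intercept = memb_intercept),
      se = list(intercept = se)
    )),
    utility = list(
      class1 = list(
        coef = list(distance_km = bd1, charges_fees = bfee1, readiness_score = bread1),
        se = list(distance_km = se, charges_fees = se, readiness_score = se)
      ),
      class2 = list(
        coef = list(distance_km = bd2, charges_fees = bfee2, readiness_score = bread2),
        se = list(distance_km = se, charges_fees = se, readiness_score = se)
      )
    )
  ))
}

# Default config scaled down for pipeline tests; model parameters untouched.
scaled_config <- function(cohort_size = 400L, n_runs = 2L,
                          n_facilities = 120L, n_nodes = 150L,
                          master_seed = 20190611L) {
  cfg <- default_config()
  cfg$cohort_size <- as.integer(cohort_size)
  cfg$n_runs <- as.integer(n_runs)
  cfg$facilities$n_facilities <- as.integer(n_facilities)
  cfg$network$n_nodes <- as.integer(n_nodes)
  cfg$master_seed <- as.integer(master_seed)
  validate_config(cfg)
}

# Random connected geometric network: a path for connectivity plus random
# chords; edge length = straight-line * detour in [1, 1.3].
random_geo_network <- function(n_nodes = 30, n_extra = 20, seed = 1) {
  withr::with_seed(seed, {
    lat <- runif(n_nodes, 0, 1)
    lon <- runif(n_nodes, 0, 1)
    path <- cbind(1:(n_nodes - 1), 2:n_nodes)
    extra <- cbind(sample.int(n_nodes, n_extra, TRUE), sample.int(n_nodes, n_extra, TRUE))
    extra <- extra[extra[, 1] != extra[, 2], , drop = FALSE]
    pairs <- rbind(path, extra)
    key <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    pairs <- pairs[!duplicated(key), , drop = FALSE]
    gap <- regiosim::haversine_km(cbind(lat[pairs[, 1]], lon[pairs[, 1]]),
                                  cbind(lat[pairs[, 2]], lon[pairs[, 2]]))
    build_network(
      tibble::tibble(id = seq_len(n_nodes), lat = lat, lon = lon),
      tibble::tibble(from = pairs[, 1], to = pairs[, 2],
                     length_km = pmax(gap, 1e-4) * runif(nrow(pairs), 1, 1.3))
    )
  })
}

# Simulate latent-class conditional-logit choices for recovery tests:
# women with wealth/literacy membership covariates pick one of J
# alternatives with per-woman random attributes. Returns the long data
# frame expected by fit_latent_class_logit() plus the generating truth.
simulate_choice_data <- function(n = 2000, J = 6, seed = 1,
                                 gamma = c(intercept = -0.4, wealth = 0.3, literacy = 0.5),
                                 beta1 = c(distance_km = -0.15, charges_fees = -2.0,
                                           readiness_score = 0.5),
                                 beta2 = c(distance_km = -0.03, charges_fees = -0.3,
                                           readiness_score = 2.5)) {
  withr::with_seed(seed, {
    wealth <- sample.int(5, n, TRUE)
    literacy <- as.numeric(runif(n) < 0.6)
    pi2 <- stats::plogis(gamma[["intercept"]] + gamma[["wealth"]] * wealth +
                           gamma[["literacy"]] * literacy)
    cls <- 1L + (runif(n) < pi2)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      x <- cbind(distance_km = runif(J, 2, 60),
                 charges_fees = as.numeric(runif(J) < 0.4),
                 readiness_score = runif(J, 0.1, 1))
      b <- if (cls[i] == 1L) beta1 else beta2
      v <- drop(x %*% b)
      p <- exp(v - max(v)); p <- p / sum(p)
      y <- sample.int(J, 1, prob = p)
      rows[[i]] <- tibble::tibble(
        woman_id = i, alt = seq_len(J), chosen = seq_len(J) == y,
        distance_km = x[, 1], charges_fees = x[, 2], readiness_score = x[, 3],
        wealth = wealth[i], literacy = literacy[i]
      )
    }
    list(data = dplyr::bind_rows(rows), class = cls,
         truth = list(gamma = gamma, beta1 = beta1, beta2 = beta2))
  })
}
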