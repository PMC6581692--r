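cfg <- default_config()

test_that("readiness score is the unweighted item mean", {
  expect_equal(readiness_score(rep(TRUE, 8)), 1)
  expect_equal(readiness_score(rep(FALSE, 8)), 0)
  expect_equal(readiness_score(c(rep(TRUE, 7), rep(FALSE, 3))), 0.7)
  expect_error(readiness_score(logical(0)), "non-empty")
})

test_that("synthetic registries have the documented structure", {
  reg <- generate_synthetic_facilities(cfg, 540, seed = 7)
  expect_equal(nrow(reg), 540)
  expect_true(all(table(reg$ftype) >= 1)) # every type represented
  expect_identical(reg, generate_synthetic_facilities(cfg, 540, seed = 7))
  expect_true(all(reg$readiness_score >= 0 & reg$readiness_score <= 1))
  # score is the mean of the stored item indicators
  items <- as.matrix(reg[grep("^item_", names(reg))])
  expect_equal(reg$readiness_score, unname(rowMeans(items)))
  # central and district hospitals are caesarean-capable under the defaults
  hosp <- reg$ftype %in% c("central_hospital", "district_hospital")
  expect_true(all(reg$cemonc_capable[hosp]))
  # fees concentrate outside the public sector
  expect_gt(mean(reg$charges_fees[reg$management != "public"]),
            mean(reg$charges_fees[reg$management == "public"]))
})

test_that("an all-health-centre registry has no caesarean capability", {
  cfg_hc <- cfg
  cfg_hc$facilities$type_probs <- list(
    central_hospital = 0, district_hospital = 0, rural_community_hospital = 0,
    other_hospital = 0, health_centre = 1, clinic = 0, maternity = 0)
  reg <- generate_synthetic_facilities(cfg_hc, 5, seed = 1)
  expect_true(all(reg$ftype == "health_centre"))
  expect_false(any(reg$cemonc_capable))
})

test_that("readiness correlates with urban proximity across seeds", {
  for (s in 1:20) {
    reg <- generate_synthetic_facilities(cfg, 540, seed = 40 + s)
    expect_gt(cor(reg$readiness_score, -reg$dist_to_urban_km), 0)
  }
})

test_that("eligibility filters implement the restriction rules exactly", {
  reg <- toy_facilities(3, cemonc = c(TRUE, FALSE, FALSE), bemonc = c(3L, 6L, 4L))
  s1 <- list(name = "s1", restriction = "cemonc_only")
  expect_identical(eligible_facilities(reg, s1)$id, 1L)
  expect_identical(eligible_facilities(reg, list(name = "sq", restriction = "none"))$id,
                   reg$id)
  # "five or more" is an inclusive boundary
  reg2 <- toy_facilities(3, bemonc = c(4L, 5L, 6L))
  expect_identical(
    eligible_facilities(reg2, list(name = "s3", restriction = "bemonc5_only"))$id,
    c(2L, 3L))
  # lifting the restriction keeps everything
  expect_identical(
    eligible_facilities(reg, list(name = "open", restriction = "cemonc_only",
                                  restrict_after_upgrade = FALSE))$id,
    reg$id)
  none <- toy_facilities(2, cemonc = c(FALSE, FALSE))
  expect_error(eligible_facilities(none, s1), "no eligible")
})

test_that("greedy upgrade siting favours dominant candidates", {
  expect_identical(
    select_upgrades(toy_facilities(2), toy_cohort(10), "cemonc", 0, 20),
    integer(0))
  # candidate 1 near 100 women, candidate 2 near 10: k = 1 picks 1
  fac <- toy_facilities(2, lat = c(0, 5), lon = c(0, 5))
  women <- toy_cohort(110,
                      lat = c(rep(0.01, 100), rep(5.01, 10)),
                      lon = c(rep(0.01, 100), rep(5.01, 10)))
  expect_identical(select_upgrades(fac, women, "cemonc", 1, 20), 1L)
  expect_error(select_upgrades(fac, women, "cemonc", 3, 20), "exceeds")
})

test_that("greedy coverage matches exhaustive search on small instances", {
  coverage_of <- function(within, qual_rows, ids_rows) {
    covered <- if (length(qual_rows)) colSums(within[qual_rows, , drop = FALSE]) > 0 else
      rep(FALSE, ncol(within))
    for (r in ids_rows) covered <- covered | within[r, ]
    sum(covered)
  }
  n_match <- 0L
  n_inst <- 50L
  for (s in seq_len(n_inst)) {
    withr::with_seed(7000 + s, {
      n_f <- sample(6:10, 1)
      k <- sample(1:3, 1)
      fac <- toy_facilities(n_f, lat = runif(n_f, 0, 1.5), lon = runif(n_f, 0, 1.5),
                            cemonc = runif(n_f) < 0.2)
      if (sum(!fac$cemonc_capable) < k) fac$cemonc_capable[] <- FALSE
      women <- toy_cohort(120, lat = runif(120, 0, 1.5), lon = runif(120, 0, 1.5))
    })
    radius <- 25
    got <- select_upgrades(fac, women, "cemonc", k, radius)
    within <- regiosim:::haversine_cross_km(cbind(fac$lat, fac$lon),
                                            cbind(women$lat, women$lon)) <= radius
    qual_rows <- which(fac$cemonc_capable)
    cand <- which(!fac$cemonc_capable)
    combos <- utils::combn(cand, k)
    best <- max(apply(combos, 2, function(rows) coverage_of(within, qual_rows, rows)))
    greedy_cov <- coverage_of(within, qual_rows, match(got, fac$id))
    expect_gte(greedy_cov, (1 - 1 / exp(1)) * best) # classical greedy bound
    if (greedy_cov == best) n_match <- n_match + 1L
  }
  expect_gte(n_match, 45L)
})

test_that("greedy coverage is non-decreasing in k and deterministic", {
  withr::with_seed(77, {
    fac <- toy_facilities(12, lat = runif(12, 0, 1), lon = runif(12, 0, 1))
    women <- toy_cohort(200, lat = runif(200, 0, 1), lon = runif(200, 0, 1))
  })
  cov_at <- function(k) {
    ids <- select_upgrades(fac, women, "cemonc", k, 15)
    within <- regiosim:::haversine_cross_km(cbind(fac$lat, fac$lon),
                                            cbind(women$lat, women$lon)) <= 15
    sum(colSums(within[match(ids, fac$id), , drop = FALSE]) > 0)
  }
  covs <- vapply(0:4, cov_at, 0)
  expect_true(all(diff(covs) >= 0))
  expect_identical(select_upgrades(fac, women, "cemonc", 3, 15),
                   select_upgrades(fac, women, "cemonc", 3, 15))
})

test_that("apply_scenario composes upgrades, fee removal and readiness", {
  reg <- toy_facilities(4, lat = c(0, 0.5, 1, 1.5), lon = rep(0, 4),
                        cemonc = c(TRUE, FALSE, FALSE, FALSE),
                        charges_fees = c(TRUE, FALSE, TRUE, FALSE),
                        readiness = c(0.9, 0.4, 0.3, 0.2))
  women <- toy_cohort(30, lat = runif(30, 0, 1.6), lon = rep(0, 30))

  sq <- apply_scenario(reg, list(name = "status_quo", restriction = "none"))
  expect_identical(sq$registry, reg)
  expect_identical(sq$eligible_ids, reg$id)
  # idempotent for the status quo
  sq2 <- apply_scenario(sq$registry, list(name = "status_quo", restriction = "none"))
  expect_identical(sq2$registry, reg)

  nf <- apply_scenario(reg, list(name = "nf", restriction = "none", remove_fees = TRUE))
  expect_false(any(nf$registry$charges_fees))
  fr <- apply_scenario(reg, list(name = "fr", restriction = "none", full_readiness = TRUE))
  expect_true(all(fr$registry$readiness_score == 1))

  s1 <- apply_scenario(reg, list(name = "s1", restriction = "cemonc_only"))
  s2 <- apply_scenario(reg, list(name = "s2", restriction = "cemonc_only",
                                 n_upgrades = 2, upgrade_target = "cemonc",
                                 coverage_radius_km = 20),
                       population = women)
  # scenario 2's eligible set is scenario 1's plus the upgraded ids
  expect_setequal(s2$eligible_ids, union(s1$eligible_ids, s2$upgraded_ids))
  expect_true(all(s1$eligible_ids %in% s2$eligible_ids))
  # upgraded readiness is raised to at least the qualifying median
  up <- s2$registry[s2$registry$id %in% s2$upgraded_ids, ]
  expect_true(all(up$readiness_score >= median(reg$readiness_score[reg$cemonc_capable])))
})

test_that("restriction eligibility is monotone across paired scenarios", {
  reg <- generate_synthetic_facilities(cfg, 150, seed = 99)
  women <- sample_cohort(cfg, 300, seed = 99)
  pairs <- list(
    c("cemonc_only", "cemonc"),
    c("bemonc5_only", "bemonc5")
  )
  for (p in pairs) {
    base <- apply_scenario(reg, list(name = "a", restriction = p[1]))
    upg <- apply_scenario(reg, list(name = "b", restriction = p[1],
                                    n_upgrades = 5, upgrade_target = p[2]),
                          population = women)
    expect_true(all(base$eligible_ids %in% upg$eligible_ids))
  }
})

test_that("scenario-analysis specs are valid and unrestricted where stated", {
  specs <- scenario_analyses()
  expect_true(all(vapply(specs, function(s) is.character(s$name), TRUE)))
  open <- specs[[1]]
  expect_false(open$restrict_after_upgrade)
  reg <- toy_facilities(3, cemonc = c(TRUE, FALSE, FALSE))
  open$n_upgrades <- 1L # the toy registry has only two candidates
  out <- apply_scenario(reg, open, population = toy_cohort(10))
  expect_identical(out$eligible_ids, reg$id) # no restriction applied
})
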