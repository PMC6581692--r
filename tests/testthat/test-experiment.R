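test_that("pci is the mean with interpolated 2.5/97.5 percentiles", {
  expect_equal(pci(rep(7, 10)), c(mean = 7, lower = 7, upper = 7))
  p <- pci(1:1000)
  expect_equal(unname(p), c(500.5, 25.975, 975.025))
  shuffled <- withr::with_seed(3, sample(1:1000))
  expect_equal(pci(shuffled), p)
  expect_equal(unname(pci(5)), c(5, 5, 5)) # single replicate degenerates
  expect_error(pci(numeric(0)), "non-empty")
})

test_that("paired travel and utility-decrement metrics match hand counts", {
  sq <- tibble::tibble(woman_id = 1:4, distance_km = c(10, 10, 10, 10),
                       utility = c(0, 0, 0, 0), class_index = c(1L, 1L, 2L, 2L))
  expect_equal(fraction_travelling_further(sq, sq), 0)
  all_further <- dplyr::mutate(sq, distance_km = distance_km + 5)
  expect_equal(fraction_travelling_further(sq, all_further), 100)
  three <- dplyr::mutate(sq, distance_km = c(15, 20, 25, 10))
  expect_equal(fraction_travelling_further(sq, three), 75)
  expect_error(fraction_travelling_further(sq, three[1:3, ]), "paired")

  params <- toy_params(bd1 = -0.05, bd2 = -0.1)
  expect_equal(utility_decrement_km(sq, sq, params), 0)
  worse <- dplyr::mutate(sq, utility = c(-0.5, -0.5, -0.5, -0.5))
  # classes 1,1,2,2: km = 0.5/0.05, 0.5/0.05, 0.5/0.1, 0.5/0.1
  expect_equal(utility_decrement_km(sq, worse, params), mean(c(10, 10, 5, 5)))
  one <- sq[1, ]
  expect_equal(utility_decrement_km(one, dplyr::mutate(one, utility = -0.5), params), 10)
})

test_that("a deterministic toy world is hand-traceable through run_once", {
  # Two facilities on the mainland grid: a free, mid-readiness health
  # centre at the origin and a fee-charging, caesarean-capable district
  # hospital at (0.2, 0.2). Five women at known locations; deterministic
  # choice with everyone in class 1.
  net <- toy_network()
  reg <- toy_facilities(2, lat = c(0, 0.2), lon = c(0, 0.2),
                        ftype = c("health_centre", "district_hospital"),
                        charges_fees = c(FALSE, TRUE),
                        readiness = c(0.5, 1),
                        cemonc = c(FALSE, TRUE))
  women <- toy_cohort(5,
                      lat = c(0, 0, 0.2, 0.2, 0.1),
                      lon = c(0, 0.02, 0.2, 0.18, 0.1),
                      cs_need = c(FALSE, FALSE, TRUE, FALSE, FALSE))

  cfg <- default_config()
  cfg$deterministic_choice <- TRUE
  cfg$choice_model <- list(
    n_classes = 2,
    membership = list(class2 = list(coef = list(intercept = -50),
                                    se = list(intercept = 0))),
    utility = list(
      class1 = list(coef = list(distance_km = -0.1, charges_fees = -1,
                                readiness_score = 1),
                    se = list(distance_km = 0, charges_fees = 0, readiness_score = 0)),
      class2 = list(coef = list(distance_km = -0.05, charges_fees = 0,
                                readiness_score = 2),
                    se = list(distance_km = 0, charges_fees = 0, readiness_score = 0))
    )
  )
  # deterministic outcomes: caesareans certain on predicted need at capable
  # facilities, never otherwise; nobody dies
  cfg$outcome_model$caesarean$p_need <- 1
  cfg$outcome_model$caesarean$p_background <- 0
  cfg$outcome_model$mortality$intercept <- -Inf
  cfg <- validate_config(cfg)

  out <- run_once(women, reg, net, list(name = "status_quo", restriction = "none"),
                  cfg, seed = 1)
  D <- network_distances(net, cbind(women$lat, women$lon), cbind(reg$lat, reg$lon))
  v <- function(i, j) -0.1 * D[i, j] - 1 * reg$charges_fees[j] + 1 * reg$readiness_score[j]
  expected_choice <- vapply(1:5, function(i) which.max(c(v(i, 1), v(i, 2))), 0L)
  expect_identical(out$records$facility_id, reg$id[expected_choice])
  expect_equal(out$records$distance_km, D[cbind(1:5, expected_choice)])
  expect_equal(out$records$utility, vapply(1:5, function(i) v(i, expected_choice[i]), 0))
  # woman 3 needs a caesarean and reaches the capable hospital
  expect_identical(out$records$caesarean, expected_choice == 2 & women$predicted_cs_need)
  expect_false(any(out$records$neonatal_death))
  expect_equal(out$summary$nmr, 0)
  expect_equal(out$records$oop_cost_usd,
               out$records$distance_km * 2 * cfg$cost_model$transport_cost_usd_per_km +
                 ifelse(expected_choice == 2,
                        cfg$cost_model$facility_fee_usd$district_hospital +
                          cfg$cost_model$nonfee_cost_usd$district_hospital,
                        cfg$cost_model$nonfee_cost_usd$health_centre))

  # restricting to the single capable facility sends everyone there
  s1 <- run_once(women, reg, net, list(name = "s1", restriction = "cemonc_only"),
                 cfg, seed = 1, sq_records = out$records)
  expect_true(all(s1$records$facility_id == 2L))
  util <- s1$utilisation
  expect_equal(util$share_pct[util$ftype == "district_hospital"], 100)
  expect_equal(sum(util$share_pct), 100)
  # revealed preference: the restricted chosen utility can never beat the
  # unrestricted optimum, so the decrement is non-negative woman by woman
  expect_true(all(out$records$utility - s1$records$utility >= 0))
  expect_gte(s1$summary$utility_decrement_km, 0)

  # identical seeds reproduce the run exactly
  rerun <- run_once(women, reg, net, list(name = "s1", restriction = "cemonc_only"),
                    cfg, seed = 1, sq_records = out$records)
  expect_identical(rerun$summary, s1$summary)
})

test_that("the replicate experiment has coherent shapes and intervals", {
  cfg <- scaled_config(cohort_size = 300L, n_runs = 3L,
                       n_facilities = 80L, n_nodes = 100L)
  res <- run_experiment(cfg)
  expect_s3_class(res, "regiosim_result")
  expect_equal(nrow(res$runs), 5 * 3) # scenarios x runs
  expect_setequal(unique(res$runs$scenario),
                  vapply(cfg$scenarios, `[[`, "", "name"))

  # utilisation shares sum to 100 in every scenario-run
  tot <- res$utilisation %>%
    dplyr::group_by(scenario, run) %>%
    dplyr::summarise(s = sum(share_pct), .groups = "drop")
  expect_equal(tot$s, rep(100, nrow(tot)), tolerance = 1e-6)

  # interval ordering holds for every metric
  expect_true(all(res$summary$lower <= res$summary$mean + 1e-12))
  expect_true(all(res$summary$mean <= res$summary$upper + 1e-12))

  # the baseline scenario has zero paired metrics by construction
  base <- res$runs[res$runs$scenario == res$baseline, ]
  expect_true(all(base$pct_further == 0))
  expect_true(all(base$utility_decrement_km == 0))

  # summary means equal means recomputed from the per-run values
  for (m in c("nmr", "mean_oop_usd", "catastrophic_pct")) {
    recomputed <- tapply(res$runs[[m]], res$runs$scenario, mean)
    got <- res$summary[res$summary$metric == m, ]
    expect_equal(got$mean, as.numeric(recomputed[got$scenario]))
  }

  # a single-run experiment collapses its intervals onto the mean
  cfg1 <- scaled_config(cohort_size = 200L, n_runs = 1L,
                        n_facilities = 60L, n_nodes = 80L)
  res1 <- run_experiment(cfg1)
  expect_equal(res1$summary$lower, res1$summary$mean)
  expect_equal(res1$summary$upper, res1$summary$mean)
})

test_that("experiments are reproducible and write complete outputs", {
  cfg <- scaled_config(cohort_size = 200L, n_runs = 2L,
                       n_facilities = 60L, n_nodes = 80L)
  res <- run_experiment(cfg)
  res2 <- run_experiment(cfg)
  expect_equal(res$runs, res2$runs)

  dir <- withr::local_tempdir()
  write_experiment_outputs(res, dir)
  for (f in c("table1.csv", "utilisation.csv", "distance.csv", "readiness.csv",
              "catastrophic_by_quintile.csv", "runs.csv", "runlog.jsonl")) {
    expect_true(file.exists(file.path(dir, f)))
  }
  tab <- readr::read_csv(file.path(dir, "table1.csv"), show_col_types = FALSE)
  expect_equal(nrow(tab), 5) # one row per scenario, baseline included
  expect_true(all(c("nmr_decrease_per_1000_mean", "caesarean_pct_mean",
                    "utility_decrement_km_mean") %in% names(tab)))
  # table means equal per-run means recomputed independently
  s1 <- tab[tab$scenario == "scenario1_cemonc", ]
  runs1 <- res$runs[res$runs$scenario == "scenario1_cemonc", ]
  runs0 <- res$runs[res$runs$scenario == res$baseline, ]
  expect_equal(s1$caesarean_pct_mean, mean(runs1$cs_pct))
  expect_equal(s1$nmr_decrease_per_1000_mean, mean(runs0$nmr - runs1$nmr))
  log_lines <- readLines(file.path(dir, "runlog.jsonl"))
  expect_length(log_lines, 2)
  expect_equal(jsonlite::fromJSON(log_lines[1])$run, 1)

  # header-only table for an empty result
  empty <- res
  empty$runs <- res$runs[0, ]
  f <- withr::local_tempfile(fileext = ".csv")
  write_results_table(empty, f)
  expect_equal(nrow(readr::read_csv(f, show_col_types = FALSE)), 0)

  # plots build without error
  expect_s3_class(plot_utilisation(res), "ggplot")
  expect_s3_class(plot_catastrophic_by_quintile(res), "ggplot")
  expect_s3_class(plot_distance_readiness(res), "ggplot")
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})

test_that("common random numbers make paired contrasts tighter than unpaired", {
  cfg <- scaled_config(cohort_size = 250L, n_runs = 8L,
                       n_facilities = 80L, n_nodes = 100L)
  res <- run_experiment(cfg)
  sq <- res$runs[res$runs$scenario == res$baseline, ]
  sc <- res$runs[res$runs$scenario == "scenario1_cemonc", ]
  for (m in c("nmr", "mean_distance_km")) {
    paired_var <- var(sc[[m]] - sq[[m]])
    perms <- withr::with_seed(91, replicate(50, var(sc[[m]] - sample(sq[[m]]))))
    expect_lte(paired_var, mean(perms))
  }
})
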