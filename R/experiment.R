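# Replicate-run orchestration. Each run index draws one cohort and one
# perturbed choice-parameter set, shared by every scenario (common random
# numbers), so per-run scenario contrasts are paired. Facility choice is
# sampled with the Gumbel-max construction: one Gumbel draw per
# (woman, facility) per run, reused across scenarios, makes the sampled
# choice exactly a draw from the conditional-logit probabilities while
# keeping scenarios maximally comparable.

RUN_METRICS <- c(
  "nmr", "cs_pct", "mean_distance_km", "pct_further", "extra_km",
  "mean_readiness", "mean_oop_usd", "catastrophic_pct",
  "utility_decrement_km", "class1_share_pct", "fallback_pct", "rescue_pct"
)

# Agent-level shared randomness for one run.
agent_draws <- function(n_women, n_facilities) {
  list(
    u_class = runif(n_women),
    gumbel = matrix(rgumbel(n_women * n_facilities), n_women, n_facilities),
    u_cs = runif(n_women),
    u_death = runif(n_women)
  )
}

sample_class_indices <- function(cohort, params, u_class) {
  pi_m <- class_membership_probs(cohort, params)
  cum <- row_cumsum(pi_m)
  as.integer(1L + rowSums(u_class > cum[, -ncol(cum), drop = FALSE]))
}

# Core single-scenario evaluation over a whole cohort, fully vectorised.
# D/fb: cohort x registry road-distance matrix and fallback flags;
# sw: applied scenario (registry', eligible_ids); sq: baseline records.
eval_scenario_run <- function(cohort, sw, registry_ids, D, fb, params, draws,
                              config, scenario_name, sq = NULL) {
  n <- nrow(cohort)
  elig_cols <- match(sw$eligible_ids, registry_ids)
  m <- length(elig_cols)
  Dm <- D[, elig_cols, drop = FALSE]
  within <- Dm <= config$choice_set_radius_km
  no_opt <- rowSums(within) == 0
  rescue <- no_opt
  if (any(no_opt)) {
    nearest <- max.col(-Dm[no_opt, , drop = FALSE], ties.method = "first")
    within[cbind(which(no_opt), nearest)] <- TRUE
  }

  class_index <- sample_class_indices(cohort, params, draws$u_class)
  reg <- sw$registry[elig_cols, , drop = FALSE]
  V <- matrix(0, n, m)
  for (c_i in seq_len(params$n_classes)) {
    rows <- class_index == c_i
    if (!any(rows)) next
    coef <- params$utility[[c_i]]$coef
    a <- facility_attr_utility(reg, coef)
    V[rows, ] <- Dm[rows, , drop = FALSE] * coef[["distance_km"]] +
      matrix(a, sum(rows), m, byrow = TRUE)
  }
  total <- if (params$deterministic) V else V + draws$gumbel[, elig_cols, drop = FALSE]
  total[!within] <- -Inf
  j <- max.col(total, ties.method = "first")
  pick <- cbind(seq_len(n), j)
  fac <- reg[j, , drop = FALSE]

  distance_km <- Dm[pick]
  utility <- V[pick]
  fallback <- fb[cbind(seq_len(n), elig_cols[j])]

  # outcomes, sharing the per-woman uniforms across scenarios
  caesarean <- caesarean_delivered(cohort, fac, config$outcome_model, u = draws$u_cs)
  death <- neonatal_death(cohort, fac, caesarean, config$outcome_model, u = draws$u_death)
  oop <- out_of_pocket_cost(fac, distance_km, config$cost_model)
  catastrophic <- is_catastrophic(oop, cohort$yearly_expenditure_usd,
                                  config$catastrophic_threshold)
  ftype_chr <- as.character(fac$ftype)

  records <- tibble(
    woman_id = cohort$id, scenario = scenario_name,
    facility_id = fac$id, ftype = ftype_chr, class_index = class_index,
    distance_km = distance_km, fallback = fallback, rescue = rescue,
    caesarean = caesarean, neonatal_death = death,
    oop_cost_usd = unname(oop), catastrophic = catastrophic,
    utility = utility, wealth_quintile = cohort$wealth_quintile
  )

  base <- sq %||% records
  decrement <- willingness_to_travel_km(base$utility - records$utility,
                                        params, class_index)
  summary <- tibble(
    scenario = scenario_name,
    nmr = mean(death) * 1000,
    cs_pct = mean(caesarean) * 100,
    mean_distance_km = mean(distance_km),
    pct_further = mean(distance_km > base$distance_km) * 100,
    extra_km = mean(distance_km) - mean(base$distance_km),
    mean_readiness = mean(fac$readiness_score),
    mean_oop_usd = mean(oop),
    catastrophic_pct = mean(catastrophic) * 100,
    utility_decrement_km = mean(decrement),
    class1_share_pct = mean(class_index == 1L) * 100,
    fallback_pct = mean(fallback) * 100,
    rescue_pct = mean(rescue) * 100
  )
  utilisation <- records %>%
    dplyr::count(.data$ftype) %>%
    mutate(share_pct = 100 * .data$n / sum(.data$n)) %>%
    tidyr::complete(ftype = FACILITY_TYPES, fill = list(n = 0L, share_pct = 0)) %>%
    mutate(scenario = scenario_name) %>%
    select("scenario", "ftype", "share_pct")
  by_quintile <- records %>%
    group_by(wealth_quintile = .data$wealth_quintile) %>%
    summarise(catastrophic_pct = 100 * mean(.data$catastrophic), .groups = "drop") %>%
    tidyr::complete(wealth_quintile = 1:5, fill = list(catastrophic_pct = 0)) %>%
    mutate(scenario = scenario_name) %>%
    select("scenario", "wealth_quintile", "catastrophic_pct")

  list(records = records, summary = summary, utilisation = utilisation,
       by_quintile = by_quintile)
}

#' Simulate one scenario for one cohort
#'
#' The full per-woman sequence for a single replicate: draw a perturbed
#' choice-parameter set, assign each woman a latent class, build her choice
#' set over the scenario-eligible facilities (road distances, 100 km
#' radius, nearest-facility rescue), sample her delivery facility, and
#' simulate caesarean delivery, neonatal death and out-of-pocket cost.
#'
#' @param cohort Cohort tibble from [sample_cohort()].
#' @param registry Facility tibble (pre-scenario).
#' @param network `regiosim_network`.
#' @param scenario Scenario spec list.
#' @param config Full `regiosim_config`.
#' @param seed Integer seed for this run's parameter and agent draws.
#' @param sq_records Optional baseline (status-quo) records from the same
#'   cohort and seed, for the paired travelling-further and
#'   utility-decrement metrics.
#' @param siting_population Cohort used for maximal-coverage upgrade siting
#'   (defaults to `cohort`).
#' @return List with `summary` (one-row tibble), `records` (one row per
#'   woman), `utilisation` and `by_quintile` tibbles.
#' @export
run_once <- function(cohort, registry, network, scenario, config, seed,
                     sq_records = NULL, siting_population = cohort) {
  scenario <- normalize_scenario(scenario)
  sw <- apply_scenario(registry, scenario, population = siting_population)
  D <- network_distances(network, cbind(cohort$lat, cohort$lon),
                         cbind(registry$lat, registry$lon))
  fb <- attr(D, "fallback")
  withr::with_seed(seed, {
    params <- draw_param_set(choice_params(config))
    params$deterministic <- isTRUE(config$deterministic_choice)
    draws <- agent_draws(nrow(cohort), nrow(registry))
    out <- eval_scenario_run(cohort, sw, registry$id, D, fb, params, draws,
                             config, scenario$name, sq = sq_records)
  })
  out$summary$run <- NA_integer_
  out
}

#' Run the full replicate experiment
#'
#' Runs every configured scenario `n_runs` times. Each run index draws a
#' fresh cohort and one perturbed choice-parameter set shared by all
#' scenarios of that run (common random numbers), with the first configured
#' scenario serving as the comparison baseline for the paired metrics.
#' Scenario restrictions and maximal-coverage upgrades are applied once,
#' against a dedicated siting cohort, before the replicate loop.
#'
#' @param config A `regiosim_config`.
#' @param world Optional list with `registry` and `network`; generated
#'   synthetically from the config (seeds derived from the master seed)
#'   when omitted.
#' @param keep_records Keep the final run's per-woman records for
#'   inspection (default `FALSE`).
#' @return A `regiosim_result`: per-run summaries (`runs`), per-run
#'   utilisation and quintile breakdowns, aggregated means with 95%
#'   posterior credible intervals (`summary`, `utilisation`,
#'   `catastrophic_by_quintile`), paired per-run contrasts vs the baseline
#'   (`contrasts`), the scenario worlds and the run log. Has [tidy()],
#'   [glance()], [autoplot()][ggplot2::autoplot] and print methods.
#' @examples
#' \donttest{
#' cfg <- default_config()
#' cfg$cohort_size <- 500L; cfg$n_runs <- 3L
#' cfg$facilities$n_facilities <- 80L; cfg$network$n_nodes <- 120L
#' res <- run_experiment(validate_config(cfg))
#' tidy(res)
#' }
#' @export
run_experiment <- function(config, world = NULL, keep_records = FALSE) {
  config <- validate_config(config)
  master <- config$master_seed
  if (is.null(world)) {
    world <- list(
      registry = generate_synthetic_facilities(
        config, seed = derive_run_seed(master, "facilities", 0)),
      network = generate_synthetic_network(
        config, seed = derive_run_seed(master, "network", 0))
    )
  }
  registry <- world$registry
  network <- world$network
  siting_n <- min(config$cohort_size, 5000L)
  siting_cohort <- sample_cohort(config, siting_n,
                                 derive_run_seed(master, "siting", 0))
  scen_worlds <- lapply(config$scenarios, function(sc) {
    sw <- apply_scenario(registry, sc, population = siting_cohort)
    sw$spec <- normalize_scenario(sc)
    sw
  })
  scen_names <- vapply(config$scenarios, `[[`, "", "name")
  baseline <- scen_names[1]

  runs <- list(); util <- list(); quint <- list(); runlog <- list()
  last_records <- NULL
  for (r in seq_len(config$n_runs)) {
    cohort <- sample_cohort(config, config$cohort_size,
                            derive_run_seed(master, "cohort", r))
    params <- withr::with_seed(derive_run_seed(master, "params", r), {
      p <- draw_param_set(choice_params(config))
      p$deterministic <- isTRUE(config$deterministic_choice)
      p
    })
    draws <- withr::with_seed(derive_run_seed(master, "agents", r),
                              agent_draws(nrow(cohort), nrow(registry)))
    D <- network_distances(network, cbind(cohort$lat, cohort$lon),
                           cbind(registry$lat, registry$lon))
    fb <- attr(D, "fallback")
    sq_records <- NULL
    run_records <- list()
    for (s in seq_along(scen_worlds)) {
      out <- eval_scenario_run(cohort, scen_worlds[[s]], registry$id, D, fb,
                               params, draws, config, scen_names[s],
                               sq = sq_records)
      if (s == 1) sq_records <- out$records
      out$summary$run <- r
      out$utilisation$run <- r
      out$by_quintile$run <- r
      runs[[length(runs) + 1L]] <- out$summary
      util[[length(util) + 1L]] <- out$utilisation
      quint[[length(quint) + 1L]] <- out$by_quintile
      if (keep_records) run_records[[s]] <- out$records
    }
    if (keep_records) last_records <- bind_rows(run_records)
    runlog[[r]] <- list(run = r,
                        cohort_seed = derive_run_seed(master, "cohort", r),
                        params_seed = derive_run_seed(master, "params", r),
                        agents_seed = derive_run_seed(master, "agents", r))
  }
  runs <- bind_rows(runs)

  long <- tidyr::pivot_longer(runs, dplyr::all_of(RUN_METRICS),
                              names_to = "metric", values_to = "value")
  summarise_pci <- function(df) {
    df %>%
      summarise(mean = mean(.data$value),
                lower = unname(quantile(.data$value, 0.025)),
                upper = unname(quantile(.data$value, 0.975)),
                .groups = "drop")
  }
  summary <- long %>%
    group_by(.data$scenario, .data$metric) %>%
    summarise_pci()
  base_long <- long %>%
    filter(.data$scenario == baseline) %>%
    select("run", "metric", base_value = "value")
  contrasts <- long %>%
    filter(.data$scenario != baseline) %>%
    left_join(base_long, by = c("run", "metric")) %>%
    mutate(value = .data$value - .data$base_value) %>%
    group_by(.data$scenario, .data$metric) %>%
    summarise_pci()

  structure(list(
    runs = runs,
    utilisation = bind_rows(util),
    catastrophic_by_quintile = bind_rows(quint),
    summary = summary,
    contrasts = contrasts,
    baseline = baseline,
    scenario_worlds = scen_worlds,
    records = last_records,
    runlog = runlog,
    config = config
  ), class = "regiosim_result")
}

#' Mean and 95% posterior credible interval
#'
#' Arithmetic mean with empirical 2.5th and 97.5th percentiles (linear
#' interpolation) across replicate values.
#'
#' @param values Non-empty numeric vector.
#' @return Named numeric vector `c(mean, lower, upper)`.
#' @examples
#' pci(1:1000)
#' @export
pci <- function(values) {
  if (!length(values)) abort("pci() needs a non-empty vector")
  qs <- quantile(values, c(0.025, 0.975), names = FALSE, type = 7)
  c(mean = mean(values), lower = qs[1], upper = qs[2])
}

check_paired <- function(sq_records, scenario_records) {
  by <- intersect(c("woman_id", "run"), intersect(names(sq_records), names(scenario_records)))
  joined <- dplyr::inner_join(
    sq_records, scenario_records, by = by, suffix = c("_sq", "_sc"),
    relationship = "one-to-one"
  )
  if (nrow(joined) != nrow(sq_records) || nrow(joined) != nrow(scenario_records)) {
    abort("records are not paired one-to-one by woman (and run)")
  }
  joined
}

#' Fraction of women travelling further than under the baseline
#'
#' Percentage of women whose scenario road distance strictly exceeds their
#' own status-quo distance, paired by woman id (and run), averaged over
#' runs.
#'
#' @param sq_records,scenario_records Per-woman record tibbles from
#'   [run_once()] (matching cohorts).
#' @return A percentage in `[0, 100]`.
#' @export
fraction_travelling_further <- function(sq_records, scenario_records) {
  joined <- check_paired(sq_records, scenario_records)
  further <- joined$distance_km_sc > joined$distance_km_sq
  if ("run" %in% names(joined)) {
    mean(tapply(further, joined$run, mean)) * 100
  } else {
    mean(further) * 100
  }
}

#' Population utility decrement in willingness-to-travel km
#'
#' Mean over women of the status-quo minus scenario chosen systematic
#' utility, converted to km with each woman's own class distance
#' coefficient.
#'
#' @inheritParams fraction_travelling_further
#' @param params `choice_params` (ideally the same draw used for the runs).
#' @return Mean decrement in km (positive = scenario worse).
#' @export
utility_decrement_km <- function(sq_records, scenario_records, params) {
  joined <- check_paired(sq_records, scenario_records)
  mean(willingness_to_travel_km(joined$utility_sq - joined$utility_sc,
                                params, joined$class_index_sc))
}

table1_metrics <- function(result) {
  pick <- function(df, metric_name) {
    df %>% filter(.data$metric == metric_name) %>%
      select("scenario", "mean", "lower", "upper")
  }
  scen <- unique(result$runs$scenario)
  # levels come from per-scenario summaries; changes come from paired contrasts
  nmr_dec <- pick(result$contrasts, "nmr") %>%
    mutate(mean = -.data$mean, lo = -.data$upper, hi = -.data$lower) %>%
    select("scenario", "mean", lower = "lo", upper = "hi")
  base_zero <- tibble(scenario = result$baseline, mean = 0, lower = 0, upper = 0)
  blocks <- list(
    nmr_decrease_per_1000 = bind_rows(base_zero, nmr_dec),
    pct_travelling_further = pick(result$summary, "pct_further"),
    extra_distance_km = pick(result$summary, "extra_km"),
    utility_decrement_km = pick(result$summary, "utility_decrement_km"),
    catastrophic_pct = pick(result$summary, "catastrophic_pct"),
    mean_oop_usd = pick(result$summary, "mean_oop_usd"),
    caesarean_pct = pick(result$summary, "cs_pct")
  )
  out <- tibble(scenario = scen)
  for (nm in names(blocks)) {
    blk <- blocks[[nm]]
    names(blk)[2:4] <- paste0(nm, c("_mean", "_lower", "_upper"))
    out <- left_join(out, blk, by = "scenario")
  }
  out
}

#' Write the headline results table
#'
#' One CSV row per scenario with the seven headline outcomes — neonatal
#' mortality decrease per 1000 livebirths (vs the baseline), % of women
#' travelling further, mean extra km, utility decrement in km, catastrophic
#' expenditure %, mean out-of-pocket USD, caesarean % — each as a mean with
#' 2.5th/97.5th percentile bounds.
#'
#' @param result A `regiosim_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(result, path) {
  tab <- if (nrow(result$runs)) table1_metrics(result) else {
    empty_cols <- as.list(rep(NA_real_, 21))
    names(empty_cols) <- paste0(rep(c(
      "nmr_decrease_per_1000", "pct_travelling_further", "extra_distance_km",
      "utility_decrement_km", "catastrophic_pct", "mean_oop_usd",
      "caesarean_pct"), each = 3), c("_mean", "_lower", "_upper"))
    tibble(scenario = character(0), !!!empty_cols)[0, ]
  }
  readr::write_csv(tab, path)
  invisible(path)
}

#' Write all experiment output tables
#'
#' Writes into `dir`: `table1.csv` (headline outcomes), `utilisation.csv`
#' (delivery share by facility type), `distance.csv` and `readiness.csv`
#' (per-run travel distance and accessed readiness),
#' `catastrophic_by_quintile.csv`, `runs.csv` (every per-run summary) and
#' `runlog.jsonl` (one JSON line per run with its derived seeds).
#'
#' @param result A `regiosim_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment_outputs <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_results_table(result, file.path(dir, "table1.csv"))
  util <- result$utilisation %>%
    group_by(.data$scenario, .data$ftype) %>%
    summarise(mean = mean(.data$share_pct),
              lower = unname(quantile(.data$share_pct, 0.025)),
              upper = unname(quantile(.data$share_pct, 0.975)), .groups = "drop")
  readr::write_csv(util, file.path(dir, "utilisation.csv"))
  readr::write_csv(
    result$runs %>% select("scenario", "run", "mean_distance_km", "extra_km", "pct_further"),
    file.path(dir, "distance.csv"))
  readr::write_csv(
    result$runs %>% select("scenario", "run", "mean_readiness"),
    file.path(dir, "readiness.csv"))
  cbq <- result$catastrophic_by_quintile %>%
    group_by(.data$scenario, .data$wealth_quintile) %>%
    summarise(mean = mean(.data$catastrophic_pct),
              lower = unname(quantile(.data$catastrophic_pct, 0.025)),
              upper = unname(quantile(.data$catastrophic_pct, 0.975)), .groups = "drop")
  readr::write_csv(cbq, file.path(dir, "catastrophic_by_quintile.csv"))
  readr::write_csv(result$runs, file.path(dir, "runs.csv"))
  con <- file(file.path(dir, "runlog.jsonl"), "w")
  for (entry in result$runlog) {
    writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE), con)
  }
  close(con)
  invisible(dir)
}

#' @export
print.regiosim_result <- function(x, ...) {
  cat(sprintf("<regiosim_result> %d scenario(s) x %d run(s), cohort %d, baseline '%s'\n",
              length(unique(x$runs$scenario)), max(x$runs$run), x$config$cohort_size,
              x$baseline))
  print(tidy(x), n = 20)
  invisible(x)
}

#' Tidy an experiment result
#'
#' @param x A `regiosim_result`.
#' @param contrasts Return paired per-run contrasts against the baseline
#'   scenario instead of per-scenario levels.
#' @param ... Unused.
#' @return Tibble with `scenario`, `metric`, `mean`, `lower`, `upper`
#'   (95% posterior credible interval bounds).
#' @method tidy regiosim_result
#' @export
tidy.regiosim_result <- function(x, contrasts = FALSE, ...) {
  if (contrasts) x$contrasts else x$summary
}

#' Glance at an experiment result
#'
#' @param x A `regiosim_result`.
#' @param ... Unused.
#' @return One-row tibble: scenario/run counts, cohort size, baseline
#'   neonatal mortality and caesarean rate.
#' @method glance regiosim_result
#' @export
glance.regiosim_result <- function(x, ...) {
  base <- x$runs %>% filter(.data$scenario == x$baseline)
  tibble(
    n_scenarios = length(unique(x$runs$scenario)),
    n_runs = max(x$runs$run),
    cohort_size = x$config$cohort_size,
    baseline_nmr = mean(base$nmr),
    baseline_cs_pct = mean(base$cs_pct),
    baseline_catastrophic_pct = mean(base$catastrophic_pct)
  )
}
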