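FACILITY_TYPES <- c(
  "central_hospital", "district_hospital", "rural_community_hospital",
  "other_hospital", "health_centre", "clinic", "maternity"
)
MANAGEMENT_TYPES <- c("public", "ngo", "private")
RESTRICTIONS <- c("none", "cemonc_only", "bemonc5_only")
UPGRADE_TARGETS <- c("none", "cemonc", "bemonc5")

default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "regiosim", mustWork = TRUE)
}

#' Default simulation configuration
#'
#' Reads the packaged defaults: a 20 000-woman cohort, 200 replicate runs,
#' a 100 km choice-set radius, a 10% catastrophic-expenditure threshold and
#' a mean yearly consumption expenditure of 137 USD, together with the
#' synthetic population, facility, road-network, choice, outcome and cost
#' models and the five packaged policy scenarios.
#'
#' @return A validated `regiosim_config` list.
#' @examples
#' cfg <- default_config()
#' cfg$cohort_size
#' @export
default_config <- function() {
  cfg <- yaml::read_yaml(default_config_path())
  validate_config(cfg)
}

# Recursive merge of `user` over `base`. Unnamed lists (e.g. scenarios,
# urban_centres) and scalars are replaced wholesale.
merge_config <- function(base, user) {
  if (is.list(user) && length(user) == 0) return(base)
  if (!is.list(base) || !is.list(user) ||
      is.null(names(base)) || is.null(names(user))) {
    return(user)
  }
  for (key in names(user)) {
    base[[key]] <- if (key %in% names(base)) {
      merge_config(base[[key]], user[[key]])
    } else {
      user[[key]]
    }
  }
  base
}

#' Load and validate a simulation configuration
#'
#' Reads a YAML or JSON configuration file and merges it over the packaged
#' defaults, so a minimal file (even `{}`) yields a fully specified,
#' validated configuration. Lists of scenarios supplied by the user replace
#' the default scenario list; each scenario is filled with per-scenario
#' defaults (no restriction, no upgrades, fees and readiness untouched).
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file, or `NULL` for the
#'   packaged defaults.
#' @return A validated `regiosim_config` list.
#' @examples
#' cfg <- load_config() # defaults
#' tmp <- tempfile(fileext = ".yaml")
#' writeLines("catastrophic_threshold: 0.25", tmp)
#' load_config(tmp)$catastrophic_threshold
#' @export
load_config <- function(path = NULL) {
  base <- yaml::read_yaml(default_config_path())
  if (is.null(path)) return(validate_config(base))
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(user)) user <- list()
  if (!is.list(user)) abort("config file must contain a mapping of keys to values")
  validate_config(merge_config(base, user))
}

scenario_defaults <- function() {
  list(
    name = NULL, restriction = "none", n_upgrades = 0L,
    upgrade_target = "none", restrict_after_upgrade = TRUE,
    remove_fees = FALSE, full_readiness = FALSE, coverage_radius_km = 20
  )
}

normalize_scenario <- function(spec) {
  if (!is.list(spec) || is.null(spec$name)) {
    abort("every scenario must be a mapping with at least a 'name'")
  }
  unknown <- setdiff(names(spec), names(scenario_defaults()))
  if (length(unknown)) {
    abort(sprintf("scenario '%s' has unknown keys: %s", spec$name,
                  paste(unknown, collapse = ", ")))
  }
  out <- modifyList(scenario_defaults(), spec)
  if (!out$restriction %in% RESTRICTIONS) {
    abort(sprintf("scenario '%s': restriction must be one of %s", out$name,
                  paste(RESTRICTIONS, collapse = ", ")))
  }
  if (!out$upgrade_target %in% UPGRADE_TARGETS) {
    abort(sprintf("scenario '%s': upgrade_target must be one of %s", out$name,
                  paste(UPGRADE_TARGETS, collapse = ", ")))
  }
  out$n_upgrades <- as.integer(out$n_upgrades)
  if (out$n_upgrades < 0) abort(sprintf("scenario '%s': n_upgrades must be >= 0", out$name))
  if (out$upgrade_target == "none" && out$n_upgrades > 0) {
    abort(sprintf("scenario '%s': n_upgrades > 0 requires an upgrade_target", out$name))
  }
  if (out$coverage_radius_km <= 0) {
    abort(sprintf("scenario '%s': coverage_radius_km must be > 0", out$name))
  }
  out
}

check_positive_count <- function(x, key) {
  if (is.null(x) || length(x) != 1 || is.na(x) || x < 1 || x != round(x)) {
    abort(sprintf("config key '%s' must be a positive integer", key))
  }
}

check_positive_real <- function(x, key) {
  if (is.null(x) || length(x) != 1 || is.na(x) || x <= 0) {
    abort(sprintf("config key '%s' must be a positive number", key))
  }
}

#' Validate a configuration list
#'
#' Enforces the configuration invariants: positive counts and radii, a
#' catastrophic threshold strictly between 0 and 1, wealth-quintile
#' marginals summing to 1, coefficient/standard-error blocks that agree,
#' negative distance coefficients in every preference class, and unique
#' scenario names.
#'
#' @param config A configuration list (as parsed from YAML/JSON).
#' @return The config, normalised, with class `regiosim_config`.
#' @export
validate_config <- function(config) {
  if (!is.list(config)) abort("config must be a list")
  check_positive_count(config$cohort_size, "cohort_size")
  check_positive_count(config$n_runs, "n_runs")
  check_positive_real(config$choice_set_radius_km, "choice_set_radius_km")
  check_positive_real(config$mean_yearly_expenditure_usd, "mean_yearly_expenditure_usd")
  ct <- config$catastrophic_threshold
  if (is.null(ct) || length(ct) != 1 || is.na(ct) || ct <= 0 || ct >= 1) {
    abort("config key 'catastrophic_threshold' must lie strictly between 0 and 1")
  }
  if (is.null(config$master_seed)) abort("config key 'master_seed' is required")
  config$cohort_size <- as.integer(config$cohort_size)
  config$n_runs <- as.integer(config$n_runs)
  config$master_seed <- as.integer(config$master_seed)

  pop <- config$population
  if (is.null(pop)) abort("config key 'population' is required")
  wm <- unlist(pop$wealth_quintile_marginals)
  if (length(wm) != 5 || any(wm < 0) || abs(sum(wm) - 1) > 1e-6) {
    abort("config key 'population.wealth_quintile_marginals' must be 5 non-negative values summing to 1")
  }
  us <- pop$urban_share
  if (is.null(us) || us < 0 || us > 1) {
    abort("config key 'population.urban_share' must lie in [0, 1]")
  }
  qm <- unlist(pop$expenditure$quintile_means)
  if (length(qm) != 5 || any(qm <= 0)) {
    abort("config key 'population.expenditure.quintile_means' must be 5 positive values")
  }

  # choice model: coef/se blocks must align and distance must deter
  cm <- config$choice_model
  if (is.null(cm)) abort("config key 'choice_model' is required")
  if (is.null(cm$n_classes) || cm$n_classes < 2) {
    abort("config key 'choice_model.n_classes' must be >= 2")
  }
  if (length(cm$membership) != cm$n_classes - 1) {
    abort("config key 'choice_model.membership' must have one block per non-reference class")
  }
  if (length(cm$utility) != cm$n_classes) {
    abort("config key 'choice_model.utility' must have one block per class")
  }
  for (blk_name in names(cm$utility)) {
    blk <- cm$utility[[blk_name]]
    if (!setequal(names(blk$coef), names(blk$se))) {
      abort(sprintf("config key 'choice_model.utility.%s': coef and se name different terms", blk_name))
    }
    if (is.null(blk$coef$distance_km) || blk$coef$distance_km >= 0) {
      abort(sprintf("config key 'choice_model.utility.%s.coef.distance_km' must be negative", blk_name))
    }
  }
  for (blk_name in names(cm$membership)) {
    blk <- cm$membership[[blk_name]]
    if (!setequal(names(blk$coef), names(blk$se))) {
      abort(sprintf("config key 'choice_model.membership.%s': coef and se name different terms", blk_name))
    }
  }

  om <- config$outcome_model
  if (is.null(om$caesarean) ||
      om$caesarean$p_need < 0 || om$caesarean$p_need > 1 ||
      om$caesarean$p_background < 0 || om$caesarean$p_background > 1) {
    abort("config key 'outcome_model.caesarean' probabilities must lie in [0, 1]")
  }

  cstm <- config$cost_model
  if (any(unlist(cstm$facility_fee_usd) < 0) || any(unlist(cstm$nonfee_cost_usd) < 0) ||
      cstm$transport_cost_usd_per_km < 0) {
    abort("config key 'cost_model' components must be non-negative")
  }

  scen <- config$scenarios
  if (is.null(scen) || !length(scen)) abort("config key 'scenarios' must list at least one scenario")
  config$scenarios <- lapply(scen, normalize_scenario)
  nms <- vapply(config$scenarios, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    abort(sprintf("config key 'scenarios': duplicate scenario name '%s'", nms[duplicated(nms)][1]))
  }

  structure(config, class = c("regiosim_config", "list"))
}

#' @export
print.regiosim_config <- function(x, ...) {
  cat("<regiosim_config>\n")
  cat(sprintf("  cohort_size: %d   n_runs: %d   master_seed: %d\n",
              x$cohort_size, x$n_runs, x$master_seed))
  cat(sprintf("  choice-set radius: %g km   catastrophic threshold: %g\n",
              x$choice_set_radius_km, x$catastrophic_threshold))
  cat(sprintf("  scenarios: %s\n",
              paste(vapply(x$scenarios, `[[`, "", "name"), collapse = ", ")))
  invisible(x)
}

#' Write a configuration to YAML
#'
#' Inverse of [load_config()]: the written file reloads to an identical
#' configuration.
#'
#' @param config A `regiosim_config`.
#' @param path Output file path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  yaml::write_yaml(x, path)
  invisible(path)
}
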