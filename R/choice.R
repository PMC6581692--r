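# Two-step latent-class discrete choice: a multinomial logit assigns each
# woman to an unobserved preference class from her own characteristics;
# conditional on class, a conditional logit over the facilities in her
# choice set (linear utility in road distance, fees, readiness and facility
# type) gives the facility choice probabilities. Coefficients and their
# standard errors live in the configuration; the packaged defaults encode
# two classes — a majority class dominated by distance and fees, and a
# minority class drawn to central hospitals and high readiness.

#' Normalise choice-model parameters
#'
#' Converts the `choice_model` configuration block into a `choice_params`
#' object: per-class named coefficient and standard-error vectors for the
#' class-membership and facility-utility models.
#'
#' @param x A `choice_model` config block, a full `regiosim_config`, or an
#'   existing `choice_params` object (returned unchanged).
#' @return A `choice_params` list.
#' @export
choice_params <- function(x) {
  if (inherits(x, "choice_params")) return(x)
  if (inherits(x, "regiosim_config") || !is.null(x$choice_model)) x <- x$choice_model
  if (is.null(x$n_classes)) abort("not a choice_model block: missing n_classes")
  as_block <- function(b) list(coef = unlist(b$coef), se = unlist(b$se)[names(unlist(b$coef))])
  out <- list(
    n_classes = as.integer(x$n_classes),
    membership = lapply(x$membership, as_block),
    utility = lapply(x$utility, as_block),
    deterministic = isTRUE(x$deterministic_choice)
  )
  for (blk in out$utility) {
    if (blk$coef[["distance_km"]] >= 0) abort("distance_km coefficient must be negative in every class")
  }
  structure(out, class = "choice_params")
}

# Design matrix for membership terms; unknown terms must be cohort columns.
membership_design <- function(women, terms) {
  women <- as_tibble(women)
  cols <- lapply(terms, function(tm) {
    switch(tm,
      intercept = rep(1, nrow(women)),
      anc_any = as.numeric(women$anc_visits > 0),
      {
        if (!tm %in% names(women)) abort(sprintf("membership term '%s' is not a cohort column", tm))
        as.numeric(women[[tm]])
      }
    )
  })
  m <- do.call(cbind, cols)
  colnames(m) <- terms
  m
}

# Facility-side design matrix: distance, fee flag, readiness, type dummies.
utility_design <- function(facilities, distance_km, terms) {
  facilities <- as_tibble(facilities)
  cols <- lapply(terms, function(tm) {
    if (tm == "distance_km") return(as.numeric(distance_km))
    if (grepl("^ftype_", tm)) {
      return(as.numeric(as.character(facilities$ftype) == sub("^ftype_", "", tm)))
    }
    if (!tm %in% names(facilities)) abort(sprintf("utility term '%s' is not a facility column", tm))
    as.numeric(facilities[[tm]])
  })
  m <- do.call(cbind, cols)
  colnames(m) <- terms
  m
}

# Facility attribute utility excluding the distance term (vector over rows).
facility_attr_utility <- function(facilities, coef) {
  terms <- setdiff(names(coef), "distance_km")
  x <- utility_design(facilities, distance_km = 0, terms = terms)
  drop(x %*% coef[terms])
}

#' Latent-class membership probabilities
#'
#' Multinomial-logit probabilities of belonging to each preference class,
#' with class 1 as the reference (linear predictor 0), from the woman's
#' wealth, literacy, parity, antenatal care, predicted risky delivery and
#' predicted caesarean need (the terms named in the configuration).
#'
#' @param women Cohort tibble (one or more rows).
#' @param params `choice_params` (or anything [choice_params()] accepts).
#' @return Matrix `nrow(women) x n_classes` of probabilities; rows sum to 1.
#' @export
class_membership_probs <- function(women, params) {
  params <- choice_params(params)
  women <- as_tibble(women)
  lp <- matrix(0, nrow(women), params$n_classes)
  for (c_i in seq_along(params$membership)) {
    blk <- params$membership[[c_i]]
    x <- membership_design(women, names(blk$coef))
    lp[, c_i + 1L] <- drop(x %*% blk$coef)
  }
  m <- apply(lp, 1, max)
  e <- exp(lp - m)
  e / rowSums(e)
}

#' Build a woman's choice set
#'
#' All eligible facilities whose road travel distance is within
#' `radius_km` (100 km by default). If the radius excludes every eligible
#' facility, the single nearest one is included instead and the set is
#' flagged as rescued, so remote women are never stranded by a
#' restriction.
#'
#' @param woman One-row cohort tibble.
#' @param eligible Eligible facility tibble (non-empty).
#' @param network `regiosim_network` used for road distances.
#' @param radius_km Choice-set radius in road km.
#' @param distances Optional precomputed vector of road distances from the
#'   woman to each row of `eligible` (skips routing).
#' @return The facility tibble with `distance_km` and `fallback` columns
#'   and a logical attribute `"rescue"`.
#' @export
build_choice_set <- function(woman, eligible, network = NULL, radius_km = 100,
                             distances = NULL) {
  if (!nrow(eligible)) abort("eligible facility set is empty")
  if (is.null(distances)) {
    if (is.null(network)) abort("either a network or precomputed distances is required")
    d <- network_distances(network, cbind(woman$lat, woman$lon),
                           cbind(eligible$lat, eligible$lon))
    distances <- drop(d)
    fallback <- drop(attr(d, "fallback"))
  } else {
    fallback <- attr(distances, "fallback") %||% rep(FALSE, length(distances))
  }
  keep <- distances <= radius_km
  rescue <- !any(keep)
  if (rescue) keep <- seq_along(distances) == which.min(distances)
  out <- eligible[keep, , drop = FALSE]
  out$distance_km <- distances[keep]
  out$fallback <- fallback[keep]
  attr(out, "rescue") <- rescue
  out
}

#' Conditional-logit facility choice probabilities
#'
#' Class-conditional softmax of the linear utility
#' `V_j = beta_class . (distance_km, fees, readiness, type dummies)`,
#' computed with max-subtraction for overflow safety.
#'
#' @param woman One-row cohort tibble (unused by the default utility terms;
#'   kept for signature symmetry and custom terms).
#' @param class_index Preference class (1-based).
#' @param cset Choice set from [build_choice_set()].
#' @param params `choice_params`.
#' @return Probability vector over the rows of `cset`, summing to 1.
#' @export
facility_choice_probs <- function(woman, class_index, cset, params) {
  params <- choice_params(params)
  if (!nrow(cset)) abort("choice set is empty")
  coef <- params$utility[[class_index]]$coef
  v <- drop(utility_design(cset, cset$distance_km, names(coef)) %*% coef)
  softmax(v)
}

#' Assign a delivery facility to one woman
#'
#' Samples a preference class from the membership probabilities, then a
#' facility from the class-conditional choice probabilities (or takes the
#' most likely facility when the model is configured deterministic), using
#' the current RNG stream. The realised systematic utility of the chosen
#' facility is recorded for later utility-decrement accounting.
#'
#' @inheritParams facility_choice_probs
#' @param cset Choice set from [build_choice_set()].
#' @return List with `class_index`, `facility_id`, `utility` and the
#'   per-facility `probs`.
#' @export
assign_delivery <- function(woman, cset, params) {
  params <- choice_params(params)
  pi_c <- class_membership_probs(woman, params)[1, ]
  class_index <- sample.int(params$n_classes, 1, prob = pi_c)
  probs <- facility_choice_probs(woman, class_index, cset, params)
  j <- if (params$deterministic) which.max(probs) else
    sample.int(nrow(cset), 1, prob = probs)
  coef <- params$utility[[class_index]]$coef
  v <- drop(utility_design(cset[j, ], cset$distance_km[j], names(coef)) %*% coef)
  list(class_index = class_index, facility_id = cset$id[j],
       utility = unname(v), probs = probs)
}

#' Convert a utility difference to willingness-to-travel km
#'
#' Divides a systematic-utility difference by the magnitude of the class's
#' distance coefficient: the number of km a woman would have to be moved
#' closer to her facility to offset the utility loss.
#'
#' @param delta_utility Numeric vector of utility differences.
#' @param params `choice_params`.
#' @param class_index Integer vector of classes (recycled against
#'   `delta_utility`).
#' @return Numeric vector of km.
#' @examples
#' cfg <- default_config()
#' willingness_to_travel_km(0.5, cfg, 1)
#' @export
willingness_to_travel_km <- function(delta_utility, params, class_index) {
  params <- choice_params(params)
  bd <- vapply(params$utility, function(b) b$coef[["distance_km"]], 0)
  if (any(bd[unique(class_index)] == 0)) abort("distance coefficient must be non-zero")
  unname(delta_utility / abs(bd[class_index]))
}

#' Draw a perturbed parameter set
#'
#' Perturbs every membership and utility coefficient with an independent
#' normal draw at its standard error (the parameter-uncertainty layer of
#' the replicate runs). Distance coefficients are constrained negative by
#' resampling.
#'
#' @param params `choice_params` with standard errors.
#' @return A new `choice_params` with perturbed coefficients and the same
#'   standard errors.
#' @export
draw_param_set <- function(params) {
  params <- choice_params(params)
  perturb <- function(blk) {
    blk$coef <- blk$coef + rnorm(length(blk$coef), 0, blk$se)
    blk
  }
  params$membership <- lapply(params$membership, perturb)
  params$utility <- lapply(params$utility, function(blk) {
    repeat {
      out <- perturb(blk)
      if (out$coef[["distance_km"]] < 0) return(out)
    }
  })
  params
}
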