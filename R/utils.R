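# Earth radius used throughout (km); great-circle distances only.
EARTH_RADIUS_KM <- 6371

as_latlon_matrix <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) != 2) abort("a coordinate must be a (lat, lon) pair")
    x <- matrix(x, ncol = 2)
  }
  x <- as.matrix(x)
  if (ncol(x) != 2) abort("coordinates must have two columns: lat, lon")
  if (any(abs(x[, 1]) > 90, na.rm = TRUE) || any(abs(x[, 2]) > 180, na.rm = TRUE)) {
    abort("invalid coordinates: |lat| <= 90 and |lon| <= 180 required")
  }
  storage.mode(x) <- "double"
  x
}

#' Great-circle distance in kilometres
#'
#' Haversine distance between points on a sphere of radius 6371 km. Both
#' arguments are `(lat, lon)` pairs in decimal degrees, either length-2
#' vectors or two-column matrices; matrices are recycled row-wise.
#'
#' @param a,b Coordinates: numeric `(lat, lon)` vectors or matrices with
#'   columns `lat`, `lon`.
#' @return Numeric vector of distances in km.
#' @examples
#' haversine_km(c(0, 0), c(0, 1)) # one degree of longitude at the equator
#' @export
haversine_km <- function(a, b) {
  a <- as_latlon_matrix(a)
  b <- as_latlon_matrix(b)
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  p1 <- a[ai, 1] * pi / 180
  p2 <- b[bi, 1] * pi / 180
  dphi <- (b[bi, 1] - a[ai, 1]) * pi / 180
  dlam <- (b[bi, 2] - a[ai, 2]) * pi / 180
  h <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(sqrt(h), 1))
}

# Cross-distance matrix (nrow(p) x nrow(q)) of haversine km.
haversine_cross_km <- function(p, q) {
  p <- as_latlon_matrix(p)
  q <- as_latlon_matrix(q)
  phi_p <- p[, 1] * pi / 180
  phi_q <- q[, 1] * pi / 180
  lam_p <- p[, 2] * pi / 180
  lam_q <- q[, 2] * pi / 180
  dphi <- outer(phi_p, phi_q, "-")
  dlam <- outer(lam_p, lam_q, "-")
  h <- sin(dphi / 2)^2 + outer(cos(phi_p), cos(phi_q)) * sin(dlam / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(sqrt(h), 1))
}

# Overflow-safe softmax of a numeric vector of utilities.
softmax <- function(v) {
  m <- max(v)
  e <- exp(v - m)
  e / sum(e)
}

# Standard Gumbel draws; adding these to systematic utilities and taking the
# argmax samples from the softmax (the Gumbel-max construction), which lets
# replicate scenarios share one set of draws per (woman, facility).
rgumbel <- function(n) -log(-log(runif(n)))

# Deterministic 31-bit string hash (djb2 variant reduced mod a Mersenne prime).
hash_string31 <- function(s) {
  h <- 5381
  for (code in utf8ToInt(s)) h <- (h * 33 + code) %% 2147483647
  h
}

#' Derive a per-run random seed
#'
#' Maps `(master_seed, scenario_name, run_index)` to a positive 31-bit seed
#' through a multiplicative hash, so each scenario/run pair gets its own
#' reproducible stream while runs with equal index can share cohorts across
#' scenarios (common random numbers).
#'
#' @param master_seed Integer master seed for the whole experiment.
#' @param scenario_name Character scalar naming the stream (scenario name or
#'   an internal stream label such as `"cohort"`).
#' @param run_index Non-negative integer replicate index.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @examples
#' derive_run_seed(42, "status_quo", 0)
#' @export
derive_run_seed <- function(master_seed, scenario_name, run_index) {
  if (length(master_seed) != 1 || is.na(master_seed)) abort("master_seed must be a single integer")
  if (length(scenario_name) != 1 || !is.character(scenario_name)) {
    abort("scenario_name must be a single string")
  }
  if (length(run_index) != 1 || is.na(run_index) || run_index < 0) {
    abort("run_index must be a single non-negative integer")
  }
  m <- 2147483647 # 2^31 - 1, prime
  mult <- 48271   # full-period multiplier mod m, keeps products < 2^53
  x <- ((as.numeric(master_seed) %% m) + m) %% m
  x <- (x * mult + 1) %% m
  x <- ((x + hash_string31(scenario_name)) * mult) %% m
  x <- ((x + as.numeric(run_index)) * mult) %% m
  as.integer(x %% (m - 1) + 1)
}

# Row-wise cumulative sums without apply() transposes.
row_cumsum <- function(m) {
  out <- m
  if (ncol(m) > 1) for (j in 2:ncol(m)) out[, j] <- out[, j - 1] + m[, j]
  out
}

stop_if_missing_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required columns: %s", what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
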