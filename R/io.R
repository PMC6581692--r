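# Plain-text interchange for the three synthetic registries. Column layouts
# are fixed and documented here; all files are UTF-8 CSV with '.' decimals.

COHORT_COLS <- c(
  "id", "lat", "lon", "urban", "wealth_quintile", "literacy", "education",
  "parity", "age_years", "married", "anc_visits", "multiple_gestation",
  "risky_delivery", "predicted_cs_need", "yearly_expenditure_usd"
)

FACILITY_BASE_COLS <- c(
  "id", "lat", "lon", "ftype", "management", "charges_fees",
  "readiness_score", "cemonc_capable", "bemonc_count_3mo"
)

#' Read and write cohort tables
#'
#' A cohort is a tibble with one row per woman and the documented columns
#' (id, location, urbanicity, wealth quintile, literacy, education, parity,
#' age, marital status, antenatal visits, multiple gestation, risky
#' delivery, predicted caesarean need, yearly expenditure in USD).
#'
#' @param cohort Cohort tibble from [sample_cohort()].
#' @param path CSV file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` the
#'   cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  stop_if_missing_cols(cohort, COHORT_COLS, "cohort")
  readr::write_csv(cohort[COHORT_COLS], path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stop_if_missing_cols(out, COHORT_COLS, "cohort file")
  out$id <- as.integer(out$id)
  out
}

#' Read and write facility registries
#'
#' One row per delivery facility: location, type (one of the seven levels of
#' the health system), management (public/NGO/private), whether delivery
#' fees are charged, the obstetric readiness score in `[0, 1]` with its
#' underlying item indicators (`item_1` ... `item_k`), caesarean capability
#' and the count of basic emergency obstetric and neonatal care signal
#' functions performed in the preceding 3 months.
#'
#' @param registry Facility tibble from [generate_synthetic_facilities()].
#' @param path CSV file path.
#' @return `write_facilities()` returns `path` invisibly; `read_facilities()`
#'   the registry tibble.
#' @export
write_facilities <- function(registry, path) {
  stop_if_missing_cols(registry, FACILITY_BASE_COLS, "facility registry")
  item_cols <- grep("^item_\\d+$", names(registry), value = TRUE)
  readr::write_csv(registry[c(FACILITY_BASE_COLS, item_cols)], path)
  invisible(path)
}

#' @rdname write_facilities
#' @export
read_facilities <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stop_if_missing_cols(out, FACILITY_BASE_COLS, "facility file")
  out$id <- as.integer(out$id)
  out$ftype <- factor(out$ftype, levels = FACILITY_TYPES)
  if (anyNA(out$ftype)) abort("facility file contains unknown facility types")
  out$bemonc_count_3mo <- as.integer(out$bemonc_count_3mo)
  out
}

#' Export facilities as GeoJSON points
#'
#' Writes a GeoJSON `FeatureCollection` of facility point locations for
#' inspection in any GIS viewer. Coordinates follow the GeoJSON order
#' `(lon, lat)`.
#'
#' @param registry Facility tibble.
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_facilities_geojson <- function(registry, path) {
  stop_if_missing_cols(registry, FACILITY_BASE_COLS, "facility registry")
  features <- lapply(seq_len(nrow(registry)), function(i) {
    row <- registry[i, ]
    list(
      type = "Feature",
      geometry = list(type = "Point", coordinates = c(row$lon, row$lat)),
      properties = list(
        id = row$id, ftype = as.character(row$ftype),
        management = row$management, charges_fees = row$charges_fees,
        readiness_score = row$readiness_score,
        cemonc_capable = row$cemonc_capable,
        bemonc_count_3mo = row$bemonc_count_3mo
      )
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write road networks as node/edge CSV
#'
#' Nodes: `id, lat, lon`. Edges: `from, to, length_km` (undirected). The
#' written pair of files round-trips through [build_network()].
#'
#' @param network A `regiosim_network`.
#' @param nodes_path,edges_path CSV file paths.
#' @return `write_network()` returns the two paths invisibly;
#'   `read_network()` a `regiosim_network`.
#' @export
write_network <- function(network, nodes_path, edges_path) {
  readr::write_csv(network$nodes[c("id", "lat", "lon")], nodes_path)
  readr::write_csv(network$edges[c("from", "to", "length_km")], edges_path)
  invisible(c(nodes_path, edges_path))
}

#' @rdname write_network
#' @export
read_network <- function(nodes_path, edges_path) {
  nodes <- readr::read_csv(nodes_path, show_col_types = FALSE, progress = FALSE)
  edges <- readr::read_csv(edges_path, show_col_types = FALSE, progress = FALSE)
  build_network(nodes, edges)
}

#' Read road edges from GeoJSON LineStrings
#'
#' Accepts a `FeatureCollection` of `LineString` features; each segment
#' between consecutive coordinates becomes one undirected edge, with
#' shared endpoints (to 1e-7 degrees) merged into single nodes. Segment
#' length is the haversine distance scaled by an optional `length_km`
#' property ratio when a feature carries a total `length_km`.
#'
#' @param path `.geojson` file of LineString features.
#' @return A `regiosim_network`.
#' @export
read_edges_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features)) abort("GeoJSON file has no features")
  key <- function(lat, lon) sprintf("%.7f_%.7f", lat, lon)
  node_env <- new.env(parent = emptyenv())
  nodes <- list()
  get_node <- function(lat, lon) {
    k <- key(lat, lon)
    if (is.null(node_env[[k]])) {
      id <- length(nodes) + 1L
      node_env[[k]] <- id
      nodes[[id]] <<- c(lat = lat, lon = lon)
    }
    node_env[[k]]
  }
  edges <- list()
  for (f in gj$features) {
    if (!identical(f$geometry$type, "LineString")) next
    coords <- f$geometry$coordinates
    seg_hav <- numeric(0)
    ids <- integer(0)
    for (c_i in coords) {
      ids <- c(ids, get_node(c_i[[2]], c_i[[1]]))
    }
    if (length(ids) < 2) next
    pts <- do.call(rbind, nodes[ids])
    seg_hav <- haversine_km(pts[-nrow(pts), , drop = FALSE], pts[-1, , drop = FALSE])
    total <- f$properties$length_km
    scale <- if (!is.null(total) && sum(seg_hav) > 0) total / sum(seg_hav) else 1
    for (s in seq_len(length(ids) - 1)) {
      edges[[length(edges) + 1L]] <- tibble(
        from = ids[s], to = ids[s + 1], length_km = unname(seg_hav[s] * scale)
      )
    }
  }
  node_tbl <- tibble(
    id = seq_along(nodes),
    lat = vapply(nodes, `[[`, 0, "lat"),
    lon = vapply(nodes, `[[`, 0, "lon")
  )
  build_network(node_tbl, bind_rows(edges))
}
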