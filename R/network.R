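# Road-network routing. The network is an undirected igraph with node
# coordinates; per-query routes use A* with a haversine heuristic
# (admissible because no edge may be shorter than the straight-line gap
# between its endpoints), and bulk origin-destination distances use
# single-source Dijkstra over the same weights, which returns identical
# distances. Locations snapping to different connected components fall back
# to the straight-line distance.

#' Build a road network from node and edge tables
#'
#' @param nodes Tibble/data frame with columns `id, lat, lon`.
#' @param edges Tibble/data frame with columns `from, to, length_km`
#'   (undirected). Edges must have positive length and may not be shorter
#'   than the haversine distance between their endpoints by more than 1%
#'   (no faster-than-straight-line roads).
#' @return A `regiosim_network`: list with `nodes` (including a
#'   `component` label), `edges`, the `igraph` object and an adjacency
#'   index used by the router.
#' @export
build_network <- function(nodes, edges) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  stop_if_missing_cols(nodes, c("id", "lat", "lon"), "node table")
  stop_if_missing_cols(edges, c("from", "to", "length_km"), "edge table")
  nodes$id <- as.integer(nodes$id)
  if (anyDuplicated(nodes$id)) abort("node ids must be unique")
  nodes <- arrange(nodes, .data$id)
  if (nrow(edges)) {
    edges$from <- as.integer(edges$from)
    edges$to <- as.integer(edges$to)
    dangling <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(dangling)) {
      abort(sprintf("edge endpoints not in node table: %s",
                    paste(head(dangling, 5), collapse = ", ")))
    }
    if (any(edges$length_km <= 0)) abort("edge lengths must be positive")
    idx <- match(edges$from, nodes$id)
    jdx <- match(edges$to, nodes$id)
    gap <- haversine_km(cbind(nodes$lat[idx], nodes$lon[idx]),
                        cbind(nodes$lat[jdx], nodes$lon[jdx]))
    bad <- edges$length_km < gap * 0.99
    if (any(bad)) {
      b <- which(bad)[1]
      abort(sprintf(
        "edge %d-%d is shorter than the straight-line distance (%.3f < %.3f km)",
        edges$from[b], edges$to[b], edges$length_km[b], gap[b]))
    }
  }
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges$from), to = as.character(edges$to),
                   weight = edges$length_km),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$id))
  )
  comp <- igraph::components(g)
  nodes$component <- comp$membership[as.character(nodes$id)]

  # adjacency index for the A* router: per node, neighbour rows + weights
  n <- nrow(nodes)
  adj_n <- vector("list", n)
  adj_w <- vector("list", n)
  for (v in seq_len(n)) {
    adj_n[[v]] <- integer(0)
    adj_w[[v]] <- numeric(0)
  }
  if (nrow(edges)) {
    idx <- match(edges$from, nodes$id)
    jdx <- match(edges$to, nodes$id)
    for (e in seq_len(nrow(edges))) {
      adj_n[[idx[e]]] <- c(adj_n[[idx[e]]], jdx[e])
      adj_w[[idx[e]]] <- c(adj_w[[idx[e]]], edges$length_km[e])
      adj_n[[jdx[e]]] <- c(adj_n[[jdx[e]]], idx[e])
      adj_w[[jdx[e]]] <- c(adj_w[[jdx[e]]], edges$length_km[e])
    }
  }
  structure(list(nodes = nodes, edges = edges, graph = g,
                 adj_n = adj_n, adj_w = adj_w),
            class = "regiosim_network")
}

#' @export
print.regiosim_network <- function(x, ...) {
  cat(sprintf("<regiosim_network> %d nodes, %d edges, %d component(s)\n",
              nrow(x$nodes), nrow(x$edges), max(x$nodes$component)))
  invisible(x)
}

#' Snap points to their nearest network node
#'
#' Nearest node by haversine distance; ties break to the lowest node id.
#'
#' @param points `(lat, lon)` vector or two-column matrix.
#' @param network A `regiosim_network`.
#' @return Integer vector of node ids, one per point.
#' @export
snap_to_network <- function(points, network) {
  if (!nrow(network$nodes)) abort("cannot snap to an empty network")
  pts <- as_latlon_matrix(points)
  d <- haversine_cross_km(pts, cbind(network$nodes$lat, network$nodes$lon))
  # nodes are stored sorted by id, so the first minimum is the lowest id
  network$nodes$id[max.col(-d, ties.method = "first")]
}

# A* between node row indices; heuristic = 0.99 * haversine to the goal
# (the 1% slack mirrors the edge-metric tolerance, keeping it admissible).
astar_nodes <- function(network, from_idx, to_idx) {
  nodes <- network$nodes
  n <- nrow(nodes)
  goal <- c(nodes$lat[to_idx], nodes$lon[to_idx])
  h <- 0.99 * haversine_km(cbind(nodes$lat, nodes$lon), goal)
  gscore <- rep(Inf, n)
  fscore <- rep(Inf, n)
  came <- integer(n)
  open <- rep(FALSE, n)
  closed <- rep(FALSE, n)
  gscore[from_idx] <- 0
  fscore[from_idx] <- h[from_idx]
  open[from_idx] <- TRUE
  while (any(open)) {
    f_open <- ifelse(open, fscore, Inf)
    cur <- which.min(f_open)
    if (cur == to_idx) break
    open[cur] <- FALSE
    closed[cur] <- TRUE
    nbrs <- network$adj_n[[cur]]
    wts <- network$adj_w[[cur]]
    for (k in seq_along(nbrs)) {
      v <- nbrs[k]
      if (closed[v]) next
      tentative <- gscore[cur] + wts[k]
      if (tentative < gscore[v]) {
        gscore[v] <- tentative
        fscore[v] <- tentative + h[v]
        came[v] <- cur
        open[v] <- TRUE
      }
    }
  }
  if (!is.finite(gscore[to_idx])) return(NULL)
  path <- to_idx
  while (path[1] != from_idx) path <- c(came[path[1]], path)
  list(path = nodes$id[path], km = gscore[to_idx])
}

#' Shortest travel route between two locations
#'
#' Snaps origin and destination to their nearest network nodes and runs A*
#' search with a haversine heuristic over edge lengths. The reported
#' distance adds the two straight-line access legs (origin to its node,
#' node to destination). If the snapped nodes lie in different connected
#' components (island locations), the route falls back to the pure
#' straight-line distance between origin and destination.
#'
#' @param network A `regiosim_network`.
#' @param origin,dest `(lat, lon)` coordinate pairs.
#' @return A `regiosim_route` list: `origin_node`, `dest_node`, `path`
#'   (node ids), `network_km`, `access_km`, `distance_km`,
#'   `fallback_used`.
#' @export
shortest_route <- function(network, origin, dest) {
  origin <- as.numeric(origin)
  dest <- as.numeric(dest)
  o_node <- snap_to_network(origin, network)
  d_node <- snap_to_network(dest, network)
  o_idx <- match(o_node, network$nodes$id)
  d_idx <- match(d_node, network$nodes$id)
  access <- haversine_km(origin, c(network$nodes$lat[o_idx], network$nodes$lon[o_idx])) +
    haversine_km(c(network$nodes$lat[d_idx], network$nodes$lon[d_idx]), dest)
  if (network$nodes$component[o_idx] != network$nodes$component[d_idx]) {
    return(structure(list(
      origin_node = o_node, dest_node = d_node, path = integer(0),
      network_km = NA_real_, access_km = NA_real_,
      distance_km = haversine_km(origin, dest), fallback_used = TRUE
    ), class = "regiosim_route"))
  }
  if (o_idx == d_idx) {
    res <- list(path = o_node, km = 0)
  } else {
    res <- astar_nodes(network, o_idx, d_idx)
  }
  structure(list(
    origin_node = o_node, dest_node = d_node, path = res$path,
    network_km = res$km, access_km = access,
    distance_km = res$km + access, fallback_used = FALSE
  ), class = "regiosim_route")
}

#' @export
print.regiosim_route <- function(x, ...) {
  cat(sprintf("<regiosim_route> %.2f km (%s), %d nodes\n", x$distance_km,
              if (x$fallback_used) "straight-line fallback" else "road", length(x$path)))
  invisible(x)
}

#' Bulk origin-destination travel distances
#'
#' Travel distance from every origin to every destination: straight-line
#' access legs plus the shortest network path between snapped nodes
#' (single-source Dijkstra over the same edge weights as [shortest_route()],
#' hence identical distances), with a straight-line fallback where the
#' snapped nodes are in different components.
#'
#' @param network A `regiosim_network`.
#' @param origins,dests Two-column `(lat, lon)` matrices.
#' @return Numeric matrix `nrow(origins) x nrow(dests)` of km, with a
#'   logical attribute `"fallback"` of the same shape.
#' @export
network_distances <- function(network, origins, dests) {
  origins <- as_latlon_matrix(origins)
  dests <- as_latlon_matrix(dests)
  o_nodes <- snap_to_network(origins, network)
  d_nodes <- snap_to_network(dests, network)
  uo <- sort(unique(o_nodes))
  ud <- sort(unique(d_nodes))
  nd <- igraph::distances(network$graph, v = as.character(uo),
                          to = as.character(ud), algorithm = "dijkstra")
  node_d <- nd[match(o_nodes, uo), match(d_nodes, ud), drop = FALSE]

  o_idx <- match(o_nodes, network$nodes$id)
  d_idx <- match(d_nodes, network$nodes$id)
  o_access <- haversine_km(origins, cbind(network$nodes$lat[o_idx], network$nodes$lon[o_idx]))
  d_access <- haversine_km(cbind(network$nodes$lat[d_idx], network$nodes$lon[d_idx]), dests)
  total <- node_d + outer(o_access, d_access, "+")

  fallback <- !is.finite(node_d)
  if (any(fallback)) {
    direct <- haversine_cross_km(origins, dests)
    total[fallback] <- direct[fallback]
  }
  attr(total, "fallback") <- fallback
  total
}

#' Generate a synthetic road network
#'
#' Builds a connected mainland graph (nodes drawn from the urban/rural
#' location mixture, edges from a minimum spanning tree plus k-nearest
#' neighbour links, lengths equal to the straight-line distance inflated by
#' a random detour factor) and, optionally, a small disconnected island
#' component emulating lake islands unreachable by road.
#'
#' @param config Full `regiosim_config`.
#' @param seed Integer seed.
#' @return A `regiosim_network`.
#' @export
generate_synthetic_network <- function(config, seed = 1) {
  net <- config$network
  pop <- config$population
  withr::with_seed(seed, {
    n <- net$n_nodes
    loc_pop <- pop
    loc_pop$urban_share <- net$urban_share
    loc <- sample_locations(loc_pop, n)
    pts <- cbind(loc$lat, loc$lon)
    d <- haversine_cross_km(pts, pts)

    # spanning tree for connectivity, kNN links for redundancy
    g_full <- igraph::graph_from_adjacency_matrix(d, mode = "undirected", weighted = TRUE)
    mst <- igraph::mst(g_full)
    mst_edges <- igraph::as_edgelist(mst, names = FALSE)
    knn_edges <- do.call(rbind, lapply(seq_len(n), function(v) {
      nb <- order(d[v, ])[2:(net$knn + 1)]
      cbind(v, nb)
    }))
    all_edges <- rbind(mst_edges, knn_edges)
    key <- paste(pmin(all_edges[, 1], all_edges[, 2]),
                 pmax(all_edges[, 1], all_edges[, 2]))
    all_edges <- all_edges[!duplicated(key), , drop = FALSE]
    detour <- runif(nrow(all_edges), net$detour_min, net$detour_max)
    length_km <- pmax(d[all_edges] * detour, 1e-3)

    nodes <- tibble(id = seq_len(n), lat = pts[, 1], lon = pts[, 2])
    edges <- tibble(from = all_edges[, 1], to = all_edges[, 2], length_km = length_km)

    isl <- net$island
    if (isTRUE(isl$enabled) && isl$n_nodes >= 2) {
      m <- isl$n_nodes
      ilat <- isl$lat + runif(m, -isl$radius_deg, isl$radius_deg)
      ilon <- isl$lon + runif(m, -isl$radius_deg, isl$radius_deg)
      iid <- n + seq_len(m)
      ring <- cbind(iid[-m], iid[-1])
      igap <- haversine_km(cbind(ilat[-m], ilon[-m]), cbind(ilat[-1], ilon[-1]))
      nodes <- bind_rows(nodes, tibble(id = iid, lat = ilat, lon = ilon))
      edges <- bind_rows(edges, tibble(
        from = ring[, 1], to = ring[, 2],
        length_km = pmax(igap * runif(m - 1, net$detour_min, net$detour_max), 1e-3)
      ))
    }
    build_network(nodes, edges)
  })
}
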