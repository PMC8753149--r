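#' Build a species-specific resistance surface
#'
#' Patch cells get the cost floor of 1; non-patch cells inside the potential
#' distribution take the species' per-class resistance weight; cells outside
#' the distribution are barriers (NA = impassable by default; a
#' large-finite mode is available for soft barriers).
#'
#' @param stack a `landscape_stack`.
#' @param dist the species' `potential_distribution`.
#' @param patches the species' `patch_set` (post-filter).
#' @param profile a [species_profile()]; its resistance table must cover
#'   every cover code encountered inside the distribution.
#' @param barrier `"infinite"` (impassable, default) or `"finite"`
#'   (resistance `barrier_factor`).
#' @param barrier_factor finite-barrier resistance weight.
#' @return A `resistance_surface`: list with `cost` (matrix; NA = barrier),
#'   `cell_km`, `species`, `barrier`.
#' @export
build_resistance <- function(stack, dist, patches, profile,
                             barrier = c("infinite", "finite"),
                             barrier_factor = 1000) {
  barrier <- match.arg(barrier)
  d <- grid_dim(stack)
  inside <- !is.na(dist) & dist == 1
  codes <- unique(stack$land_cover[inside])
  missing_res <- setdiff(as.character(codes), names(profile$resistance))
  if (length(missing_res)) {
    stop(sprintf("species %s: no resistance entry for encountered class(es) %s",
                 profile$species, paste(missing_res, collapse = ", ")))
  }
  cost <- matrix(NA_real_, d[1], d[2])
  cost[inside] <- profile$resistance[as.character(stack$land_cover[inside])]
  cost[patches$labels > 0L] <- 1
  if (barrier == "finite") cost[is.na(cost)] <- barrier_factor
  structure(list(cost = cost, cell_km = stack$cell_km,
                 species = profile$species, barrier = barrier),
            class = "resistance_surface")
}

## Step cost between two 8-adjacent cells: mean of the two cells' effective
## resistance times the centre-to-centre distance (cell_km, x sqrt(2) on
## diagonals). Patches traverse at zero internal cost, so patch cells take
## effective resistance 0.
lcp_edge_list <- function(cost_eff, cell_km) {
  d <- dim(cost_eff)
  n <- prod(d)
  idx <- which(!is.na(cost_eff))
  off <- neighbor_offsets(8)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  r <- ((idx - 1L) %% d[1]) + 1L
  c <- ((idx - 1L) %/% d[1]) + 1L
  for (k in seq_len(nrow(off))) {
    dr <- off[k, "dr"]; dc <- off[k, "dc"]
    ## enumerate each undirected pair once
    if (dr < 0 || (dr == 0 && dc < 0)) next
    rr <- r + dr; cc <- c + dc
    ok <- rr >= 1L & rr <= d[1] & cc >= 1L & cc <= d[2]
    a <- idx[ok]
    b <- (cc[ok] - 1L) * d[1] + rr[ok]
    keep <- !is.na(cost_eff[b])
    a <- a[keep]; b <- b[keep]
    step <- cell_km * if (dr != 0 && dc != 0) sqrt(2) else 1
    from <- c(from, a); to <- c(to, b)
    w <- c(w, (cost_eff[a] + cost_eff[b]) / 2 * step)
  }
  list(from = from, to = to, weight = w)
}

#' Least-cost distances between patches
#'
#' Minimum accumulated cost over 8-connected cell paths on the resistance
#' surface, with step cost = mean of the two cells' resistance x
#' centre-to-centre distance (diagonal steps x sqrt(2)). Patches are
#' zero-internal-cost sources: all patch cells have effective resistance 0
#' and each patch is collapsed to a single source via zero-weight edges
#' (multi-source Dijkstra, run through an explicit cell graph). Distances
#' above `max_cost` are reported unreachable.
#'
#' @param resistance a `resistance_surface`.
#' @param patches the matching `patch_set`.
#' @param max_cost cost-distance ceiling (km-equivalents); `Inf` keeps all.
#' @return List with `matrix` (symmetric cost-distance matrix, `Inf` =
#'   unreachable, patch ids as dimnames) and `table` (data frame patch_i,
#'   patch_j, cost_distance, reachable for i < j).
#' @export
least_cost_distances <- function(resistance, patches, max_cost = Inf) {
  ids <- patches$patches$id
  np <- length(ids)
  if (np < 1) stop("at least one patch is required")
  cost_eff <- resistance$cost
  for (cc in patches$cells) cost_eff[cc] <- 0
  edges <- lcp_edge_list(cost_eff, resistance$cell_km)
  n_cells <- prod(dim(cost_eff))
  ## patch supernodes appended after the cell vertices
  sup_from <- unlist(lapply(seq_len(np), function(i) {
    rep(n_cells + i, length(patches$cells[[i]]))
  }))
  sup_to <- unlist(patches$cells)
  g <- igraph::make_empty_graph(n = n_cells + np, directed = FALSE)
  g <- igraph::add_edges(g, c(rbind(edges$from, edges$to),
                              rbind(sup_from, sup_to)))
  wts <- c(edges$weight, rep(0, length(sup_from)))
  sup <- n_cells + seq_len(np)
  dmat <- igraph::distances(g, v = sup, to = sup, weights = wts,
                            algorithm = "dijkstra")
  dimnames(dmat) <- list(ids, ids)
  dmat[dmat > max_cost] <- Inf
  diag(dmat) <- 0
  tab <- NULL
  if (np >= 2) {
    pr <- utils::combn(np, 2)
    tab <- data.frame(patch_i = ids[pr[1, ]], patch_j = ids[pr[2, ]],
                      cost_distance = dmat[cbind(pr[1, ], pr[2, ])])
    tab$reachable <- is.finite(tab$cost_distance)
  } else {
    tab <- data.frame(patch_i = integer(0), patch_j = integer(0),
                      cost_distance = numeric(0), reachable = logical(0))
  }
  list(matrix = dmat, table = tab)
}

#' Build the dispersal-thresholded patch graph
#'
#' Links are retained iff their least-cost distance does not exceed the
#' species' dispersal distance. Cost units are interpreted as
#' km-equivalents (cost 1 = 1 km of ideal habitat), so the allometric
#' dispersal distance applies directly; `cost_to_km` rescales if a
#' different convention is wanted.
#'
#' @param patches a `patch_set` with quality columns ([patch_quality()]).
#' @param distances result of [least_cost_distances()].
#' @param dispersal_km the species' dispersal distance D (km), > 0.
#' @param cost_to_km km per cost unit (default 1).
#' @return A `patch_graph`: list with `species`, `nodes` (id, area_km2,
#'   quality, qa_km2), `edges` (from, to, cost_distance), `dispersal_km`.
#' @export
build_graph <- function(patches, distances, dispersal_km, cost_to_km = 1) {
  if (dispersal_km <= 0) stop("dispersal_km must be positive")
  threshold <- dispersal_km / cost_to_km
  tab <- distances$table
  keep <- tab$reachable & tab$cost_distance <= threshold
  nodes <- patches$patches[, intersect(c("id", "area_km2", "quality", "qa_km2"),
                                       names(patches$patches)), drop = FALSE]
  structure(list(species = patches$species, nodes = nodes,
                 edges = data.frame(from = tab$patch_i[keep],
                                    to = tab$patch_j[keep],
                                    cost_distance = tab$cost_distance[keep]),
                 dispersal_km = dispersal_km),
            class = "patch_graph")
}

#' @export
print.patch_graph <- function(x, ...) {
  cat(sprintf("<patch_graph> %s: %d nodes, %d links, D = %.3g km\n",
              x$species, nrow(x$nodes), nrow(x$edges), x$dispersal_km))
  invisible(x)
}
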