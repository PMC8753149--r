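## Adjacency list (by node position 1..n) from a patch graph.
graph_adjacency <- function(graph) {
  ids <- graph$nodes$id
  n <- length(ids)
  adj <- rep(list(integer(0)), n)
  if (nrow(graph$edges)) {
    fi <- match(graph$edges$from, ids)
    ti <- match(graph$edges$to, ids)
    for (k in seq_along(fi)) {
      adj[[fi[k]]] <- c(adj[[fi[k]]], ti[k])
      adj[[ti[k]]] <- c(adj[[ti[k]]], fi[k])
    }
  }
  adj
}

## Topological (link-count) shortest-path lengths from src; Inf if unreachable.
bfs_hops <- function(adj, src) {
  n <- length(adj)
  dist <- rep(Inf, n)
  dist[src] <- 0
  queue <- src; head <- 1L
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

#' Integral index of connectivity (IIC)
#'
#' The binary-connection landscape index
#' `IIC = (sum_i sum_j a_i a_j / (1 + nl_ij)) / A_L^2`, where `a_i` are
#' patch areas, `nl_ij` is the number of links on the topologically
#' shortest path between patches i and j (`nl_ii = 0`), unreachable pairs
#' contribute 0, and `A_L` is the total landscape area. IIC lies in
#' `[0, 1]`; a single patch covering the whole landscape gives 1.
#'
#' @param graph a `patch_graph`.
#' @param landscape_area_AL total landscape area `A_L` (km^2), > 0.
#' @return The IIC value.
#' @export
iic <- function(graph, landscape_area_AL) {
  if (landscape_area_AL <= 0) stop("landscape area A_L must be positive")
  a <- graph$nodes$area_km2
  n <- length(a)
  if (n == 0) return(0)
  adj <- graph_adjacency(graph)
  total <- 0
  for (i in seq_len(n)) {
    nl <- bfs_hops(adj, i)
    reach <- is.finite(nl)
    total <- total + sum(a[i] * a[reach] / (1 + nl[reach]))
  }
  total / landscape_area_AL^2
}

#' Per-patch importance dIIC
#'
#' `dIIC_k = 100 * (IIC - IIC_without_k) / IIC`: the percentage decrease in
#' landscape connectivity when patch k and its links are removed.
#'
#' @param graph a `patch_graph`.
#' @param landscape_area_AL total landscape area `A_L` (km^2).
#' @return Numeric vector of dIIC values (named by patch id).
#' @export
diic <- function(graph, landscape_area_AL) {
  full <- iic(graph, landscape_area_AL)
  if (full <= 0) stop("IIC of the full graph is 0; dIIC undefined")
  ids <- graph$nodes$id
  out <- vapply(seq_along(ids), function(k) {
    sub <- graph
    sub$nodes <- graph$nodes[-k, , drop = FALSE]
    drop <- graph$edges$from == ids[k] | graph$edges$to == ids[k]
    sub$edges <- graph$edges[!drop, , drop = FALSE]
    100 * (full - iic(sub, landscape_area_AL)) / full
  }, numeric(1))
  stats::setNames(out, ids)
}

## Dijkstra from src on the weighted patch graph; returns list(dist, sigma,
## preds): shortest distances, path counts, and predecessor lists, with a
## relative tolerance for equal-cost ties.
dijkstra_paths <- function(adj, wadj, src, tol = 1e-12) {
  n <- length(adj)
  dist <- rep(Inf, n); dist[src] <- 0
  sigma <- numeric(n); sigma[src] <- 1
  preds <- rep(list(integer(0)), n)
  done <- logical(n)
  order_out <- integer(0)
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    v <- cand[which.min(dist[cand])]
    done[v] <- TRUE
    order_out <- c(order_out, v)
    for (k in seq_along(adj[[v]])) {
      w <- adj[[v]][k]
      nd <- dist[v] + wadj[[v]][k]
      eps <- tol * max(1, abs(nd))
      if (nd < dist[w] - eps) {
        dist[w] <- nd
        sigma[w] <- sigma[v]
        preds[[w]] <- v
      } else if (abs(nd - dist[w]) <= eps) {
        sigma[w] <- sigma[w] + sigma[v]
        preds[[w]] <- c(preds[[w]], v)
      }
    }
  }
  list(dist = dist, sigma = sigma, preds = preds, order = order_out)
}

#' Betweenness centrality of patches
#'
#' `BC_k` is the sum over unordered pairs of other patches (i, j) of the
#' fraction of shortest i-j paths passing through k, with endpoints
#' excluded and unreachable pairs contributing 0. Shortest paths are
#' counted by link number (`"topological"`, default, matching the binary
#' IIC connection model) or by least-cost link weight (`"cost"`).
#' Implemented with Brandes' dependency accumulation.
#'
#' @param graph a `patch_graph`.
#' @param weighting `"topological"` or `"cost"`.
#' @return Numeric vector of BC values (named by patch id).
#' @export
betweenness_centrality <- function(graph, weighting = c("topological", "cost")) {
  weighting <- match.arg(weighting)
  ids <- graph$nodes$id
  n <- length(ids)
  bc <- numeric(n)
  if (n == 0) return(bc)
  adj <- rep(list(integer(0)), n)
  wadj <- rep(list(numeric(0)), n)
  if (nrow(graph$edges)) {
    fi <- match(graph$edges$from, ids)
    ti <- match(graph$edges$to, ids)
    wt <- if (weighting == "cost") graph$edges$cost_distance else
      rep(1, nrow(graph$edges))
    for (k in seq_along(fi)) {
      adj[[fi[k]]] <- c(adj[[fi[k]]], ti[k]); wadj[[fi[k]]] <- c(wadj[[fi[k]]], wt[k])
      adj[[ti[k]]] <- c(adj[[ti[k]]], fi[k]); wadj[[ti[k]]] <- c(wadj[[ti[k]]], wt[k])
    }
  }
  for (s in seq_len(n)) {
    sp <- dijkstra_paths(adj, wadj, s)
    delta <- numeric(n)
    for (v in rev(sp$order)) {
      for (p in sp$preds[[v]]) {
        delta[p] <- delta[p] + sp$sigma[p] / sp$sigma[v] * (1 + delta[v])
      }
      if (v != s) bc[v] <- bc[v] + delta[v]
    }
  }
  ## each unordered pair was counted from both endpoints
  stats::setNames(bc / 2, ids)
}

#' Rescale the three indices and rank patches
#'
#' Each index (BC, dIIC, QA) is min-max rescaled to `[0, 1]` across the
#' species' patches (a constant index rescales to all zeros, with a
#' message); the composite connectivity-importance score is their sum (in
#' `[0, 3]`). Patches are ranked by descending composite, ties broken by
#' larger area, then smaller patch id.
#'
#' @param graph a `patch_graph` whose nodes carry `area_km2` and `qa_km2`.
#' @param landscape_area_AL total landscape area (km^2) for dIIC.
#' @param bc_weighting passed to [betweenness_centrality()].
#' @return An `index_table` data frame: id, area_km2, bc, diic, qa, the
#'   rescaled columns (`*_s`), composite, rank.
#' @export
rescale_and_rank <- function(graph, landscape_area_AL,
                             bc_weighting = "topological") {
  ids <- graph$nodes$id
  if (!length(ids)) stop("graph has no patches")
  bc <- betweenness_centrality(graph, bc_weighting)
  di <- diic(graph, landscape_area_AL)
  qa <- graph$nodes$qa_km2 %||% graph$nodes$area_km2
  rescale <- function(v, label) {
    rng <- range(v)
    if (diff(rng) == 0) {
      message(sprintf("index %s is constant across patches; rescaled to 0", label))
      return(rep(0, length(v)))
    }
    (v - rng[1]) / diff(rng)
  }
  tab <- data.frame(id = ids, area_km2 = graph$nodes$area_km2,
                    bc = as.numeric(bc), diic = as.numeric(di),
                    qa = as.numeric(qa))
  tab$bc_s <- rescale(tab$bc, "BC")
  tab$diic_s <- rescale(tab$diic, "dIIC")
  tab$qa_s <- rescale(tab$qa, "QA")
  tab$composite <- tab$bc_s + tab$diic_s + tab$qa_s
  ord <- order(-tab$composite, -tab$area_km2, tab$id)
  tab$rank <- integer(nrow(tab))
  tab$rank[ord] <- seq_len(nrow(tab))
  tab <- tab[order(tab$rank), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("index_table", "data.frame")
  tab
}

#' Select connectivity areas up to the habitat target
#'
#' Walks the ranked patch list and selects the shortest rank prefix whose
#' cumulative area reaches `target` (default 50%) of the species' total
#' habitat area; removing the last-selected patch would drop below target.
#'
#' @param table an `index_table` from [rescale_and_rank()].
#' @param target habitat fraction to conserve, in (0, 1].
#' @return A `connectivity_areas` list: `selected_ids`, `selected_area_km2`,
#'   `total_habitat_km2`, `target`, and the table with `selected` and
#'   `cum_area_km2` columns.
#' @export
select_connectivity_areas <- function(table, target = 0.5) {
  if (target <= 0 || target > 1) stop("target must lie in (0, 1]")
  tab <- table[order(table$rank), , drop = FALSE]
  total <- sum(tab$area_km2)
  tab$cum_area_km2 <- cumsum(tab$area_km2)
  k <- match(TRUE, tab$cum_area_km2 >= target * total)
  if (is.na(k)) k <- nrow(tab)
  tab$selected <- seq_len(nrow(tab)) <= k
  structure(list(selected_ids = tab$id[tab$selected],
                 selected_area_km2 = tab$cum_area_km2[k],
                 total_habitat_km2 = total, target = target, table = tab),
            class = "connectivity_areas")
}

#' Connectivity-area mask on the grid
#'
#' @param areas a `connectivity_areas`.
#' @param patches the matching `patch_set`.
#' @return Logical matrix: cells of the selected patches.
#' @export
connectivity_mask <- function(areas, patches) {
  matrix(patches$labels %in% areas$selected_ids,
         nrow(patches$labels), ncol(patches$labels))
}
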