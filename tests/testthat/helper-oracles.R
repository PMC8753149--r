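## Independent oracles and fixture builders. Everything here is written
## against the definitions, not against the package internals: labeling by
## iterative label propagation, least-cost by exhaustive path search with
## cost-bound pruning, BC by simple-path enumeration, IIC via igraph
## shortest paths.

## --- fixtures ---------------------------------------------------------

tiny_stack <- function(rows = 16, cols = 16, seed = 1, ...) {
  generate_landscape(rows, cols, cell_km = 1, seed = seed, config = list(...))
}

default_resistance <- function() {
  c("1" = 1, "2" = 1, "3" = 2, "4" = 3, "5" = 10, "6" = 30, "7" = 100)
}

tiny_profile <- function(species = "sp1", habitat = c(1, 2, 3),
                         hr = c(1, 2, 3, 2, 1.5), ...) {
  species_profile(species, habitat_classes = habitat, home_ranges_km2 = hr,
                  resistance = default_resistance(), ...)
}

## patch graph built directly from tables (bypasses the raster stages)
make_graph <- function(areas, edges = NULL, qa = NULL, ids = seq_along(areas),
                       dispersal_km = 1e6) {
  if (is.null(edges)) {
    edges <- data.frame(from = integer(0), to = integer(0),
                        cost_distance = numeric(0))
  }
  structure(list(species = "test",
                 nodes = data.frame(id = ids, area_km2 = areas,
                                    qa_km2 = qa %||% areas),
                 edges = edges, dispersal_km = dispersal_km),
            class = "patch_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## random connected-ish test graph on n nodes
random_graph <- function(n, p = 0.4, weighted = FALSE) {
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  e <- pairs[keep, , drop = FALSE]
  edges <- data.frame(from = e[, 1], to = e[, 2],
                      cost_distance = if (weighted) runif(nrow(e), 0.5, 3)
                      else rep(1, nrow(e)))
  make_graph(areas = runif(n, 1, 10), edges = edges)
}

## --- connected-component oracle --------------------------------------

## iterative min-label propagation until fixpoint
flood_fill_oracle <- function(mask, connectivity = 8) {
  d <- dim(mask)
  m <- !is.na(mask) & mask > 0
  lab <- matrix(0L, d[1], d[2])
  lab[m] <- seq_len(sum(m))
  offs <- if (connectivity == 8) {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
         c(1, -1), c(1, 0), c(1, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  repeat {
    changed <- FALSE
    for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
      if (!m[r, c]) next
      for (o in offs) {
        rr <- r + o[1]; cc <- c + o[2]
        if (rr >= 1 && rr <= d[1] && cc >= 1 && cc <= d[2] && m[rr, cc] &&
            lab[rr, cc] < lab[r, c]) {
          lab[r, c] <- lab[rr, cc]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  ids <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], ids)
  lab
}

## --- least-cost oracle ------------------------------------------------

## exhaustive depth-first path search with cost-bound pruning; `r` is the
## effective resistance grid (NA = barrier, patch cells already zeroed);
## step cost = mean of endpoint resistances x centre distance.
lcp_oracle <- function(r, from_cells, to_cells, cell_km = 1) {
  d <- dim(r)
  n <- prod(d)
  isto <- rep(FALSE, n); isto[to_cells] <- TRUE
  visited <- rep(FALSE, n)
  best <- Inf
  nbrs <- function(i) {
    ro <- ((i - 1) %% d[1]) + 1; co <- ((i - 1) %/% d[1]) + 1
    out <- integer(0); len <- numeric(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- ro + dr; cc <- co + dc
      if (rr < 1 || rr > d[1] || cc < 1 || cc > d[2]) next
      j <- (cc - 1) * d[1] + rr
      if (is.na(r[j])) next
      out <- c(out, j)
      len <- c(len, cell_km * if (dr != 0 && dc != 0) sqrt(2) else 1)
    }
    list(cells = out, len = len)
  }
  dfs <- function(i, acc) {
    if (acc >= best) return(invisible())
    if (isto[i]) { best <<- acc; return(invisible()) }
    visited[i] <<- TRUE
    nb <- nbrs(i)
    step <- (r[i] + r[nb$cells]) / 2 * nb$len
    ord <- order(step)
    for (k in ord) {
      j <- nb$cells[k]
      if (!visited[j]) dfs(j, acc + step[k])
    }
    visited[i] <<- FALSE
    invisible()
  }
  for (s in from_cells) {
    if (!is.na(r[s])) dfs(s, 0)
  }
  best
}

## --- graph-index oracles ----------------------------------------------

graph_to_igraph <- function(graph) {
  n <- nrow(graph$nodes)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(graph$edges)) {
    idx <- cbind(match(graph$edges$from, graph$nodes$id),
                 match(graph$edges$to, graph$nodes$id))
    g <- igraph::add_edges(g, c(t(idx)))
    igraph::E(g)$weight <- graph$edges$cost_distance
  }
  g
}

iic_oracle <- function(graph, A_L) {
  g <- graph_to_igraph(graph)
  nl <- igraph::distances(g, weights = NA)  # unweighted hop counts
  a <- graph$nodes$area_km2
  tot <- 0
  n <- length(a)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (is.finite(nl[i, j])) tot <- tot + a[i] * a[j] / (1 + nl[i, j])
  }
  tot / A_L^2
}

diic_oracle <- function(graph, A_L) {
  full <- iic_oracle(graph, A_L)
  ids <- graph$nodes$id
  sapply(seq_along(ids), function(k) {
    sub <- graph
    sub$nodes <- graph$nodes[-k, , drop = FALSE]
    drop <- graph$edges$from == ids[k] | graph$edges$to == ids[k]
    sub$edges <- graph$edges[!drop, , drop = FALSE]
    100 * (full - iic_oracle(sub, A_L)) / full
  })
}

## BC by enumerating all simple paths between every pair; shortest by hop
## count (or accumulated weight), sigma / sigma(k) tallied directly.
bc_oracle <- function(graph, weighting = c("topological", "cost"), tol = 1e-9) {
  weighting <- match.arg(weighting)
  n <- nrow(graph$nodes)
  ids <- graph$nodes$id
  adj <- rep(list(integer(0)), n)
  wadj <- rep(list(numeric(0)), n)
  if (nrow(graph$edges)) {
    fi <- match(graph$edges$from, ids); ti <- match(graph$edges$to, ids)
    wt <- if (weighting == "cost") graph$edges$cost_distance
          else rep(1, nrow(graph$edges))
    for (k in seq_along(fi)) {
      adj[[fi[k]]] <- c(adj[[fi[k]]], ti[k]); wadj[[fi[k]]] <- c(wadj[[fi[k]]], wt[k])
      adj[[ti[k]]] <- c(adj[[ti[k]]], fi[k]); wadj[[ti[k]]] <- c(wadj[[ti[k]]], wt[k])
    }
  }
  bc <- numeric(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    paths <- list(); lens <- numeric(0)
    dfs <- function(v, seen, len) {
      if (v == j) {
        paths[[length(paths) + 1]] <<- seen
        lens <<- c(lens, len)
        return(invisible())
      }
      for (k in seq_along(adj[[v]])) {
        w <- adj[[v]][k]
        if (!(w %in% seen)) dfs(w, c(seen, w), len + wadj[[v]][k])
      }
      invisible()
    }
    dfs(i, i, 0)
    if (!length(paths)) next
    mn <- min(lens)
    sel <- which(lens <= mn + tol * max(1, mn))
    sigma <- length(sel)
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      through <- sum(vapply(sel, function(pidx) k %in% paths[[pidx]], logical(1)))
      bc[k] <- bc[k] + through / sigma
    }
  }
  stats::setNames(bc, ids)
}
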