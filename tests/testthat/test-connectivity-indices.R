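test_that("IIC boundary behaviour and closed-form cases", {
  ## one patch filling the landscape -> IIC = 1
  expect_equal(iic(make_graph(areas = 100), landscape_area_AL = 100), 1)
  ## two unlinked unit patches on A_L = 4: only self terms, (1+1)/16
  g2 <- make_graph(areas = c(1, 1))
  expect_equal(iic(g2, 4), 0.125)
  ## linking them adds the cross terms at one link
  g2l <- make_graph(areas = c(1, 1),
                    edges = data.frame(from = 1, to = 2, cost_distance = 1))
  expect_equal(iic(g2l, 4), (1 + 1 + 2 * (1 / 2)) / 16)
  expect_error(iic(g2, 0), "positive")
})

test_that("IIC and dIIC match brute-force oracles on random graphs", {
  set.seed(17)
  for (i in 1:30) {
    n <- sample(3:12, 1)
    g <- random_graph(n, p = runif(1, 0.2, 0.7))
    A_L <- sum(g$nodes$area_km2) * runif(1, 1, 3)
    expect_equal(iic(g, A_L), iic_oracle(g, A_L), tolerance = 1e-12)
    if (n <= 10) {
      expect_equal(unname(diic(g, A_L)), unname(diic_oracle(g, A_L)),
                   tolerance = 1e-12)
    }
  }
})

test_that("IIC stays in [0,1], grows with added patches, and dIIC >= 0", {
  set.seed(29)
  for (i in 1:20) {
    n <- sample(2:10, 1)
    g <- random_graph(n, p = 0.4)
    A_L <- sum(g$nodes$area_km2) * runif(1, 1.2, 3)
    v <- iic(g, A_L)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_true(all(diic(g, A_L) >= -1e-12))
    ## adding a patch to a fixed-A_L landscape cannot decrease IIC
    g_plus <- g
    g_plus$nodes <- rbind(g$nodes,
                          data.frame(id = n + 1, area_km2 = runif(1, 0.5, 3),
                                     qa_km2 = 1))
    expect_gte(iic(g_plus, A_L), v)
  }
})

test_that("single-node and symmetric graphs give the expected dIIC", {
  expect_equal(unname(diic(make_graph(areas = 5), 50)), 100)
  ## twin patches with identical areas and links have equal dIIC
  g <- make_graph(areas = c(2, 2, 7),
                  edges = data.frame(from = c(1, 2), to = c(3, 3),
                                     cost_distance = 1))
  d <- diic(g, 20)
  expect_equal(d[["1"]], d[["2"]])
})

test_that("betweenness matches forced cases, igraph, and path enumeration", {
  ## path A-B-C: the middle node carries the single pair
  path3 <- make_graph(areas = c(1, 1, 1),
                      edges = data.frame(from = c(1, 2), to = c(2, 3),
                                         cost_distance = 1))
  expect_equal(unname(betweenness_centrality(path3)), c(0, 1, 0))
  ## complete triangle: no intermediaries
  tri <- make_graph(areas = c(1, 1, 1),
                    edges = data.frame(from = c(1, 1, 2), to = c(2, 3, 3),
                                       cost_distance = 1))
  expect_equal(unname(betweenness_centrality(tri)), c(0, 0, 0))

  set.seed(41)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    g <- random_graph(n, p = runif(1, 0.3, 0.8), weighted = TRUE)
    ## topological: exact agreement with enumeration and igraph
    bt <- betweenness_centrality(g, "topological")
    expect_equal(unname(bt), unname(bc_oracle(g, "topological")),
                 tolerance = 1e-12)
    ig <- graph_to_igraph(g)
    expect_equal(unname(bt),
                 unname(igraph::betweenness(ig, weights = NA)),
                 tolerance = 1e-12)
    ## cost-weighted: against enumeration at 1e-9
    bw <- betweenness_centrality(g, "cost")
    expect_equal(unname(bw), unname(bc_oracle(g, "cost")), tolerance = 1e-9)
  }
})

test_that("relabeling patch ids permutes index outputs identically", {
  set.seed(5)
  g <- random_graph(6, p = 0.5)
  perm <- sample(6)
  g2 <- g
  g2$nodes$id <- perm[match(g$nodes$id, 1:6)]
  g2$edges$from <- perm[g$edges$from]
  g2$edges$to <- perm[g$edges$to]
  A_L <- 100
  expect_equal(unname(diic(g, A_L)), unname(diic(g2, A_L)))
  expect_equal(unname(betweenness_centrality(g)),
               unname(betweenness_centrality(g2)))
})

test_that("rescaling bounds the composite and ranking obeys the tie-break", {
  ## degenerate single patch: all indices constant -> composite 0, rank 1
  g1 <- make_graph(areas = 10)
  suppressMessages(t1 <- rescale_and_rank(g1, 100))
  expect_equal(t1$composite, 0)
  expect_equal(t1$rank, 1L)

  ## a patch dominating all three indices ranks first
  g <- make_graph(areas = c(10, 1, 1, 1), qa = c(10, 0.5, 0.4, 0.3),
                  edges = data.frame(from = c(2, 1, 1), to = c(1, 3, 4),
                                     cost_distance = 1))
  tab <- suppressMessages(rescale_and_rank(g, 100))
  expect_equal(tab$id[tab$rank == 1], 1)
  expect_true(all(tab$bc_s >= 0 & tab$bc_s <= 1))
  expect_true(all(tab$composite >= 0 & tab$composite <= 3))
  expect_true(all(sort(tab$rank) == seq_len(nrow(tab))))

  ## random index tables sort by (composite, area, id)
  set.seed(13)
  for (i in 1:20) {
    n <- sample(3:9, 1)
    g <- random_graph(n, 0.5)
    g$nodes$qa_km2 <- g$nodes$area_km2 * runif(n)
    tab <- suppressMessages(rescale_and_rank(g, sum(g$nodes$area_km2) * 2))
    ord <- order(-tab$composite, -tab$area_km2, tab$id)
    expect_equal(tab$rank[ord], seq_len(n))
  }
})

test_that("greedy selection meets the target minimally and nests across targets", {
  set.seed(19)
  for (i in 1:100) {
    n <- sample(2:12, 1)
    tab <- data.frame(id = 1:n, area_km2 = runif(n, 1, 20),
                      composite = runif(n))
    tab$rank <- rank(-tab$composite, ties.method = "first")
    sel <- select_connectivity_areas(tab, target = 0.5)
    total <- sum(tab$area_km2)
    expect_gte(sel$selected_area_km2, 0.5 * total)
    ## minimal prefix: dropping the last selected patch falls below target
    if (length(sel$selected_ids) > 1) {
      expect_lt(sel$selected_area_km2 -
                  sel$table$area_km2[length(sel$selected_ids)], 0.5 * total)
    }
    ## selection is a rank prefix
    ranks <- sel$table$rank[sel$table$selected]
    expect_equal(sort(ranks), seq_along(ranks))
    ## 30% nests within 50%
    sel30 <- select_connectivity_areas(tab, target = 0.3)
    expect_true(all(sel30$selected_ids %in% sel$selected_ids))
  }
  tab <- data.frame(id = 1:3, area_km2 = c(6, 3, 1), composite = c(3, 2, 1),
                    rank = 1:3)
  ## one dominant patch holding 60% suffices at 50%
  expect_equal(select_connectivity_areas(tab, 0.5)$selected_ids, 1)
  ## target 1 selects everything
  expect_equal(select_connectivity_areas(tab, 1)$selected_ids, 1:3)
  expect_error(select_connectivity_areas(tab, 0), "target")
})
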