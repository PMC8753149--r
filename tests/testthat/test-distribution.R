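test_that("spatial thinning enforces the minimum pairwise distance", {
  occ <- occurrence_set("s", c(0, 0.3), c(0, 0.4))  # 0.5 km apart
  thin <- spatial_thin(occ, 1, seed = 1)
  expect_equal(nrow(thin), 1)

  ## zero distance is the identity
  expect_identical(spatial_thin(occ, 0, seed = 1), occ)

  ## clustered + isolated points: isolated survive, cluster decongested
  set.seed(3)
  cl <- occurrence_set("s", x = runif(10, 0, 0.5), y = runif(10, 0, 0.5))
  iso <- occurrence_set("s", x = c(5, 9, 13, 17, 21), y = rep(5, 5))
  occ2 <- occurrence_set("s", c(cl$x, iso$x), c(cl$y, iso$y))
  thin2 <- spatial_thin(occ2, 1, seed = 2)
  expect_true(all(iso$x %in% thin2$x))
  dm <- as.matrix(dist(cbind(thin2$x, thin2$y)))
  diag(dm) <- Inf
  expect_true(all(dm >= 1))

  ## deterministic given the seed
  expect_identical(spatial_thin(occ2, 1, seed = 2), thin2)
})

test_that("correlated predictors are pruned by the Spearman rule", {
  st <- tiny_stack(24, 24, seed = 5)
  ## duplicated layer: exactly one of the pair survives
  st$climate$dup <- st$climate$clim1
  kept <- prune_correlated_predictors(st, c("clim1", "dup"), sample_n = 200,
                                      seed = 1)
  expect_length(kept, 1)

  ## forced structure A, B = A, C independent: C always kept
  st$climate$indep <- matrix(rnorm(24 * 24), 24, 24)
  kept2 <- prune_correlated_predictors(st, c("clim1", "dup", "indep"),
                                       sample_n = 300, seed = 1)
  expect_true("indep" %in% kept2)
  expect_length(kept2, 2)
  ## deterministic tie-break: same call, same answer
  expect_identical(prune_correlated_predictors(st, c("clim1", "dup", "indep"),
                                               sample_n = 300, seed = 1), kept2)

  ## independent noise layers are essentially never pruned at 0.8
  keeps <- vapply(1:20, function(s) {
    stn <- tiny_stack(16, 16, seed = s, climate_sigma = 0)
    length(prune_correlated_predictors(stn, sample_n = 200, seed = s))
  }, numeric(1))
  expect_gte(mean(keeps == 4), 0.95)

  expect_error(prune_correlated_predictors(st, sample_n = 5), "sample_n")
  expect_error(prune_correlated_predictors(st, c("clim1", "nope"), sample_n = 100),
               "unknown")
})

test_that("envelope model is 1 inside the presence envelope and decays outside", {
  st <- tiny_stack(16, 16, seed = 2)
  ## presences pinned to identical climate values -> suitability 1 there
  cell <- which.max(st$climate$clim1)
  xy <- connectiscape:::cell_xy(st, rep(cell, 25))
  occ <- occurrence_set("s", xy[, "x"] + runif(25, -0.4, 0.4),
                        xy[, "y"] + runif(25, -0.4, 0.4))
  ## all within one cell -> every layer envelope collapses to a point
  suit <- fit_envelope_model(occ, st, min_occurrences = 20)
  cells <- connectiscape:::xy_cell(st, occ$x, occ$y)
  expect_true(all(suit[cells] == 1))
  expect_true(all(suit >= 0 & suit <= 1))

  ## monotone penalty: values outside every presence's range score below
  ## the envelope interior
  expect_lt(suit[which.min(st$climate$clim1)], 1)

  ## too few occurrences is a typed, skippable error
  few <- occurrence_set("s", xy[1:5, "x"], xy[1:5, "y"])
  expect_error(fit_envelope_model(few, st), class = "min_occurrences_error")
})

test_that("envelope suitability recovers a known logistic truth", {
  rhos <- vapply(1:10, function(s) {
    st <- tiny_stack(24, 24, seed = s)
    truth <- 1 / (1 + exp(-3 * st$climate$clim1))
    occ <- sample_occurrences(st, truth, 60, seed = s)
    suit <- fit_envelope_model(occ, st, min_occurrences = 20)
    cor(as.vector(suit), as.vector(truth), method = "spearman")
  }, numeric(1))
  expect_gt(min(rhos), 0)
  expect_gt(mean(rhos), 0.5)
})

test_that("minimum-training-presence thresholding has zero training omission", {
  st <- tiny_stack(16, 16, seed = 4)
  ## boundary inclusive: cell at exactly the threshold is inside
  suit <- matrix(0.29, 16, 16)
  suit[1, 1] <- 0.3; suit[1, 2] <- 0.7
  xy <- connectiscape:::cell_xy(st, c(1L, 17L))  # cells (1,1) and (1,2)
  occ <- occurrence_set("s", xy[, "x"], xy[, "y"])
  pd <- threshold_mtp(suit, occ, st)
  expect_equal(attr(pd, "threshold"), 0.3)
  expect_equal(pd[1, 1], 1L)
  expect_equal(pd[2, 1], 0L)   # 0.29 < 0.3

  ## uniform suitability -> everything inside
  expect_true(all(threshold_mtp(matrix(0.5, 16, 16), occ, st) == 1L))

  ## random surface + 30 presences: training omission is exactly zero
  set.seed(9)
  suit2 <- matrix(runif(256), 16, 16)
  cells <- sample(256, 30)
  xy2 <- connectiscape:::cell_xy(st, cells)
  occ2 <- occurrence_set("s", xy2[, "x"], xy2[, "y"])
  pd2 <- threshold_mtp(suit2, occ2, st)
  expect_true(all(pd2[cells] == 1L))

  ## occurrences on no-data cells are rejected with their rows listed
  suit3 <- suit2; suit3[cells[1]] <- NA
  expect_error(threshold_mtp(suit3, occ2, st), "no-data")
})

test_that("elevation clipping is an inclusive in-band intersection", {
  st <- tiny_stack(16, 16, seed = 4)
  pd <- structure(matrix(1L, 16, 16), class = c("potential_distribution",
                                                "matrix", "array"))
  free <- tiny_profile()
  expect_equal(sum(clip_by_elevation(pd, st$elevation, free)), 256)

  ## all terrain below the band -> empty, with a warning
  low <- tiny_profile(species = "hi")
  low$elev_min_m <- max(st$elevation) + 1000
  low$elev_max_m <- Inf
  expect_warning(out <- clip_by_elevation(pd, st$elevation, low), "empty")
  expect_equal(sum(out), 0)

  ## ramp elevation: retained cells equal the brute-force in-band count
  band <- tiny_profile(species = "band")
  band$elev_min_m <- 500; band$elev_max_m <- 1500
  got <- clip_by_elevation(pd, st$elevation, band)
  want <- (st$elevation >= 500 & st$elevation <= 1500) * 1L
  expect_equal(unclass(got), want, ignore_attr = TRUE)
  ## monotone shrinkage
  expect_true(all(got <= pd))
})

test_that("the distribution stage is deterministic end to end", {
  st <- tiny_stack(24, 24, seed = 6)
  truth <- 1 / (1 + exp(-2 * st$climate$clim2))
  occ <- sample_occurrences(st, truth, 60, seed = 3)
  run1 <- {
    t1 <- spatial_thin(occ, 0.5, seed = 11)
    s1 <- fit_envelope_model(t1, st, min_occurrences = 20)
    threshold_mtp(s1, t1, st)
  }
  run2 <- {
    t2 <- spatial_thin(occ, 0.5, seed = 11)
    s2 <- fit_envelope_model(t2, st, min_occurrences = 20)
    threshold_mtp(s2, t2, st)
  }
  expect_identical(run1, run2)
})
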