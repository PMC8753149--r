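pd_all <- function(n) structure(matrix(1L, n, n),
                                class = c("potential_distribution", "matrix", "array"))

test_that("habitat mask is the cellwise conjunction of distribution and cover", {
  st <- tiny_stack(16, 16, seed = 7)
  prof <- tiny_profile()
  reg <- st$registry

  ## all-habitat cover inside an all-1 distribution -> full mask
  cover1 <- matrix(1L, 16, 16)
  expect_true(all(habitat_mask(pd_all(16), cover1, prof, reg)))

  ## empty distribution -> empty mask
  pd0 <- pd_all(16); pd0[] <- 0L
  expect_false(any(habitat_mask(pd0, cover1, prof, reg)))

  ## checkerboard: mask equals the brute-force conjunction
  cb <- matrix(rep_len(c(1L, 5L), 256), 16, 16)
  got <- habitat_mask(pd_all(16), cb, prof, reg)
  want <- matrix(cb %in% prof$habitat_classes, 16, 16)
  expect_equal(got, want)

  bad <- species_profile("odd", habitat_classes = c(1, 99),
                         home_ranges_km2 = 2,
                         resistance = c(default_resistance(), "99" = 5))
  expect_error(habitat_mask(pd_all(16), cover1, bad, reg), "99")
})

test_that("forest loss removes exactly the cells lost by the cutoff year", {
  mask <- matrix(TRUE, 10, 10)
  loss <- matrix(NA_integer_, 10, 10)
  expect_equal(apply_forest_loss(mask, loss, 2016), mask)

  loss[2, 2] <- 2010L; loss[3, 3] <- 2015L; loss[4, 4] <- 2016L
  expect_equal(apply_forest_loss(mask, loss, 2009), mask)  # before all losses
  got <- apply_forest_loss(mask, loss, 2015)
  expect_false(got[2, 2]); expect_false(got[3, 3]); expect_true(got[4, 4])

  ## random schedule: removed count equals the brute-force tally
  set.seed(5)
  m <- matrix(runif(100) < 0.6, 10, 10)
  ly <- matrix(ifelse(runif(100) < 0.3, sample(2007:2016, 100, TRUE),
                      NA_integer_), 10, 10)
  for (y in c(2008, 2012, 2016)) {
    got <- apply_forest_loss(m, ly, y)
    expect_equal(sum(m) - sum(got), sum(m & !is.na(ly) & ly <= y))
  }
})

test_that("patch labeling matches the connectivity convention and the oracle", {
  ## a filled rectangle is one patch with the full area
  rect <- matrix(TRUE, 4, 6)
  ps <- label_patches(rect, 8, cell_km = 2)
  expect_equal(nrow(ps$patches), 1)
  expect_equal(ps$patches$area_km2, 4 * 6 * 4)

  ## diagonal-touching cells: joined under 8, split under 4
  diagm <- matrix(FALSE, 3, 3); diagm[1, 1] <- diagm[2, 2] <- TRUE
  expect_equal(nrow(label_patches(diagm, 8)$patches), 1)
  expect_equal(nrow(label_patches(diagm, 4)$patches), 2)

  ## random masks agree with the independent flood-fill oracle
  set.seed(11)
  for (i in 1:50) {
    m <- matrix(runif(256) < runif(1, 0.3, 0.7), 16, 16)
    for (conn in c(4, 8)) {
      ps <- label_patches(m, conn)
      oracle <- flood_fill_oracle(m, conn)
      expect_equal(nrow(ps$patches), max(oracle))
      ## same partition up to label permutation
      expect_equal(ps$labels > 0, oracle > 0)
      tab <- table(ps$labels[m], oracle[m])
      expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
    }
  }
})

test_that("patch areas partition the mask area", {
  set.seed(2)
  m <- matrix(runif(400) < 0.5, 20, 20)
  ps <- label_patches(m, 8, cell_km = 1.5)
  expect_equal(sum(ps$patches$area_km2), sum(m) * 1.5^2)
})

test_that("home-range filtering is inclusive and monotone", {
  m <- matrix(FALSE, 12, 12)
  m[1:2, 1:2] <- TRUE      # 4 cells
  m[5:9, 5:9] <- TRUE      # 25 cells
  m[12, 12] <- TRUE        # 1 cell
  ps <- label_patches(m, 4, cell_km = 1)

  ## boundary inclusive: area exactly equal to the home range is retained
  kept <- filter_by_home_range(ps, 4)
  expect_true(4 %in% kept$patches$area_km2)
  expect_equal(nrow(kept$patches), 2)
  ## label raster consistent with the retained set
  expect_equal(sort(unique(kept$labels[kept$labels > 0])), kept$patches$id)

  ## home range above all areas -> empty set, warned
  expect_warning(none <- filter_by_home_range(ps, 1000), "no habitat patch")
  expect_equal(nrow(none$patches), 0)

  ## monotonicity: raising the home range never adds patches
  hrs <- c(0.5, 1, 4, 10, 25, 26)
  sets <- lapply(hrs, function(h) {
    suppressWarnings(filter_by_home_range(ps, h)$patches$id)
  })
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
  ## and equals the brute-force filter
  expect_equal(sets[[4]], ps$patches$id[ps$patches$area_km2 >= 10])
})

test_that("patch quality and QA follow the natural-cover tally", {
  reg <- default_cover_registry()
  m <- matrix(FALSE, 6, 6); m[1:2, 1:5] <- TRUE  # one 10-cell patch
  ps <- label_patches(m, 8, cell_km = 1)

  cover <- matrix(1L, 6, 6)
  all_nat <- patch_quality(ps, cover, reg)
  expect_equal(all_nat$patches$quality, 1)
  expect_equal(all_nat$patches$qa_km2, 10)

  ## half natural by cell count
  cover2 <- cover
  cover2[1, 1:5] <- 5L   # transformed row inside the patch
  half <- patch_quality(ps, cover2, reg)
  expect_equal(half$patches$quality, 0.5)
  expect_equal(half$patches$qa_km2, 5)
  ## binary mode: any natural cell counts as quality 1
  expect_equal(patch_quality(ps, cover2, reg, mode = "binary")$patches$qa_km2, 10)

  ## random composition equals the brute-force cell tally; QA <= area
  set.seed(8)
  for (i in 1:10) {
    mm <- matrix(runif(144) < 0.55, 12, 12)
    cv <- matrix(sample(reg$code, 144, TRUE), 12, 12)
    pq <- patch_quality(label_patches(mm, 8), cv, reg)
    nat <- matrix(cv %in% reg$code[reg$natural], 12, 12)
    for (k in seq_len(nrow(pq$patches))) {
      cells <- which(pq$labels == pq$patches$id[k])
      expect_equal(pq$patches$quality[k], mean(nat[cells]))
    }
    expect_true(all(pq$patches$qa_km2 <= pq$patches$area_km2 + 1e-12))
    expect_equal(pq$patches$qa_km2 == pq$patches$area_km2,
                 pq$patches$quality == 1)
  }
})

test_that("forest-loss statistics recount the schedule exactly", {
  m <- matrix(TRUE, 10, 10)
  loss <- matrix(NA_integer_, 10, 10)
  none <- forest_loss_stats(m, loss, 2008:2016)
  expect_true(all(none$per_year$loss_km2 == 0))
  expect_equal(none$total_pct, 0)

  ## 1 of 100 habitat cells lost in one year -> 1% that year
  loss[5, 5] <- 2010L
  one <- forest_loss_stats(m, loss, 2008:2016)
  expect_equal(one$per_year$loss_pct[one$per_year$year == 2010], 1)
  expect_equal(one$total_km2, 1)

  ## synthetic schedule: percentages equal a brute-force recount
  set.seed(3)
  ly <- matrix(ifelse(runif(100) < 0.4, sample(2008:2016, 100, TRUE),
                      NA_integer_), 10, 10)
  mb <- matrix(runif(100) < 0.7, 10, 10)
  stats <- forest_loss_stats(mb, ly, 2008:2016, cell_km = 2)
  for (y in 2008:2016) {
    expect_equal(stats$per_year$loss_km2[stats$per_year$year == y],
                 sum(mb & !is.na(ly) & ly == y) * 4)
  }
  expect_equal(stats$total_pct,
               100 * sum(mb & !is.na(ly)) / sum(mb))
})
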