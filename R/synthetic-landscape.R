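## Gaussian smoothing of a matrix by separable kernel convolution with
## reflecting edges; sigma in cells.
smooth_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  conv1 <- function(x) {
    n <- length(x)
    pad <- c(x[pmin(n, r:1)], x, x[pmax(1, n - seq_len(r) + 1)])
    out <- stats::filter(pad, k, sides = 2)
    as.numeric(out[(r + 1):(r + n)])
  }
  m <- apply(m, 2, conv1)
  t(apply(m, 1, conv1))
}

## Seeded-region-growing categorical mosaic: n_clumps seeds expand wavefront
## by wavefront in a random order, producing contiguous irregular clumps.
grow_mosaic <- function(rows, cols, n_clumps, clump_classes) {
  n <- rows * cols
  lab <- integer(n)
  seeds <- sample.int(n, n_clumps)
  lab[seeds] <- seq_len(n_clumps)
  frontier <- seeds
  off <- neighbor_offsets(4)
  while (length(frontier)) {
    frontier <- frontier[sample.int(length(frontier))]
    r <- ((frontier - 1L) %% rows) + 1L
    c <- ((frontier - 1L) %/% rows) + 1L
    cand_from <- rep(frontier, each = 4L)
    rr <- rep(r, each = 4L) + rep(off[, "dr"], times = length(frontier))
    cc <- rep(c, each = 4L) + rep(off[, "dc"], times = length(frontier))
    ok <- rr >= 1L & rr <= rows & cc >= 1L & cc <= cols
    cand <- (cc[ok] - 1L) * rows + rr[ok]
    cand_from <- cand_from[ok]
    free <- lab[cand] == 0L
    cand <- cand[free]; cand_from <- cand_from[free]
    first <- !duplicated(cand)
    cand <- cand[first]; cand_from <- cand_from[first]
    lab[cand] <- lab[cand_from]
    frontier <- cand
  }
  matrix(clump_classes[lab], rows, cols)
}

## Edge-biased erosion of forest clumps: loss spreads inward from clump
## boundaries, mimicking frontier deforestation; years drawn uniformly.
erode_forest <- function(land_cover, forest_codes, n_lose, years) {
  d <- dim(land_cover)
  forest <- matrix(land_cover %in% forest_codes, d[1], d[2])
  loss <- matrix(NA_integer_, d[1], d[2])
  lost <- matrix(FALSE, d[1], d[2])
  remaining <- n_lose
  while (remaining > 0) {
    idx <- which(forest & !lost)
    if (!length(idx)) break
    on_edge <- vapply(idx, function(i) {
      nb <- cell_neighbors(i, d[1], d[2], 4)
      any(!forest[nb] | lost[nb]) || length(nb) < 4
    }, logical(1))
    edge <- idx[on_edge]
    if (!length(edge)) edge <- idx
    take <- edge[stats::runif(length(edge)) < 0.5]
    if (!length(take)) take <- edge[sample.int(length(edge), 1)]
    if (length(take) > remaining) take <- sample(take, remaining)
    lost[take] <- TRUE
    loss[take] <- sample(years, length(take), replace = TRUE)
    remaining <- remaining - length(take)
  }
  loss
}

#' Generate a synthetic landscape stack
#'
#' Produces aligned layers with the statistical structure the analysis
#' assumes: spatially autocorrelated climate fields (Gaussian-smoothed
#' noise), a terrain gradient with autocorrelated relief, a
#' seeded-region-growing land-cover mosaic mixing natural and transformed
#' classes, edge-biased forest-loss years on forest clumps, and an
#' ecosystem-service count positively associated with natural cover.
#' Deterministic given `seed`.
#'
#' @param rows,cols grid dimensions (>= 8).
#' @param cell_km cell edge length, km.
#' @param seed integer seed; every random draw derives from it.
#' @param config named list overriding generator settings: `n_climate` (4),
#'   `climate_sigma` (3 cells), `natural_fraction` (0.6), `n_clumps`
#'   (rows*cols/64, min 8), `loss_fraction` (0.03 of forest cells),
#'   `loss_years` (2007:2016), `service_assoc` (0.4; added to the per-trial
#'   service probability on natural cells), `service_base` (0.12),
#'   `elev_range` (c(0, 3000) m), `registry` (a [cover_registry()]).
#' @return A validated [landscape_stack()].
#' @export
generate_landscape <- function(rows, cols, cell_km = 1, seed = 1L, config = list()) {
  if (rows < 8 || cols < 8) stop("rows and cols must both be >= 8")
  if (cell_km <= 0) stop("cell_km must be positive")
  reg <- config$registry %||% default_cover_registry()
  config$registry <- NULL
  cfg <- utils::modifyList(list(
    n_climate = 4L, climate_sigma = 3, natural_fraction = 0.6,
    n_clumps = max(8L, as.integer(rows * cols / 64)),
    loss_fraction = 0.03, loss_years = 2007:2016,
    service_assoc = 0.4, service_base = 0.12,
    elev_range = c(0, 3000)
  ), config)
  if (!inherits(reg, "cover_registry")) stop("config$registry must be a cover_registry")
  if (cfg$natural_fraction < 0 || cfg$natural_fraction > 1) {
    stop("natural_fraction must lie in [0, 1]")
  }
  nat_codes <- reg$code[reg$natural]
  trf_codes <- reg$code[!reg$natural]
  if (!length(nat_codes) || !length(trf_codes)) {
    stop("registry must contain both natural and transformed classes")
  }
  with_seed(seed, {
    climate <- stats::setNames(
      lapply(seq_len(cfg$n_climate), function(i) {
        f <- smooth_matrix(matrix(stats::rnorm(rows * cols), rows, cols),
                           cfg$climate_sigma)
        (f - mean(f)) / stats::sd(f)
      }),
      paste0("clim", seq_len(cfg$n_climate))
    )
    relief <- smooth_matrix(matrix(stats::rnorm(rows * cols), rows, cols),
                            cfg$climate_sigma)
    relief <- (relief - min(relief)) / max(1e-12, diff(range(relief)))
    ramp <- matrix(rep(seq(1, 0, length.out = rows), cols), rows, cols)
    elevation <- cfg$elev_range[1] +
      diff(cfg$elev_range) * (0.7 * ramp + 0.3 * relief)

    n_nat <- stats::rbinom(1, cfg$n_clumps, cfg$natural_fraction)
    clump_classes <- c(
      sample(nat_codes, n_nat, replace = TRUE),
      sample(trf_codes, cfg$n_clumps - n_nat, replace = TRUE)
    )[sample.int(cfg$n_clumps)]
    land_cover <- grow_mosaic(rows, cols, cfg$n_clumps, clump_classes)

    forest_codes <- reg$code[reg$forest]
    n_forest <- sum(land_cover %in% forest_codes)
    loss <- erode_forest(land_cover, forest_codes,
                         round(cfg$loss_fraction * n_forest), cfg$loss_years)

    natural <- matrix(land_cover %in% nat_codes, rows, cols)
    p <- cfg$service_base + cfg$service_assoc * natural
    p <- pmin(pmax(p, 0), 1)
    service <- matrix(stats::rbinom(rows * cols, 4, as.vector(p)), rows, cols)

    landscape_stack(climate, elevation, land_cover, loss, service,
                    cell_km = cell_km, registry = reg)
  })
}

#' Sample species occurrences from a known suitability truth
#'
#' Draws occurrence points at cell centres with probability proportional to
#' `truth * bias`, sampling cells without replacement, which supports
#' recovery tests of the distribution stage against a known surface.
#'
#' @param stack a `landscape_stack`.
#' @param truth matrix in `[0, 1]` on the stack grid, or a function of the
#'   stack returning one.
#' @param n number of points (must not exceed the nonzero-probability cells).
#' @param bias optional nonnegative matrix modelling survey effort.
#' @param seed integer seed.
#' @param species species id for the returned set.
#' @return An [occurrence_set()].
#' @export
sample_occurrences <- function(stack, truth, n, bias = NULL, seed = 1L,
                               species = "species_1") {
  if (n < 1) stop("n must be >= 1")
  if (is.function(truth)) truth <- truth(stack)
  d <- grid_dim(stack)
  if (!identical(dim(truth), d)) stop("truth must match the stack grid")
  if (any(truth < 0 | truth > 1, na.rm = TRUE)) stop("truth values must lie in [0, 1]")
  p <- as.vector(truth)
  if (!is.null(bias)) {
    if (!identical(dim(bias), d)) stop("bias must match the stack grid")
    if (any(bias < 0, na.rm = TRUE)) stop("bias must be nonnegative")
    p <- p * as.vector(bias)
  }
  p[is.na(p)] <- 0
  avail <- sum(p > 0)
  if (n > avail) {
    stop(sprintf("n = %d exceeds the %d cells with nonzero sampling probability",
                 n, avail))
  }
  with_seed(seed, {
    idx <- sample.int(length(p), n, replace = FALSE, prob = p)
    xy <- cell_xy(stack, idx)
    occurrence_set(species, xy[, "x"], xy[, "y"])
  })
}

#' Generate disjoint protected-area polygons
#'
#' Places `n_pas` disjoint rectangular reserves covering approximately
#' `total_fraction` of the landscape, by rejection-sampled packing on the
#' cell grid. Deterministic given `seed`.
#'
#' @param stack a `landscape_stack`.
#' @param n_pas number of polygons.
#' @param total_fraction target covered fraction of the grid, in (0, 1).
#' @param seed integer seed.
#' @param max_tries placement attempts per polygon before declaring the
#'   packing infeasible.
#' @return A `pa_polygons` list; each element has `id` and `coords` (km).
#' @export
generate_pa_polygons <- function(stack, n_pas, total_fraction, seed = 1L,
                                 max_tries = 500L) {
  if (total_fraction <= 0 || total_fraction >= 1) {
    stop("total_fraction must lie strictly between 0 and 1")
  }
  d <- grid_dim(stack)
  n_cells <- prod(d)
  target_cells <- total_fraction * n_cells
  with_seed(seed, {
    w8 <- stats::runif(n_pas, 0.75, 1.25)
    cells_per <- target_cells * w8 / sum(w8)
    occ <- matrix(FALSE, d[1], d[2])
    polys <- vector("list", n_pas)
    for (i in seq_len(n_pas)) {
      aspect <- stats::runif(1, 0.6, 1.6)
      w <- max(1L, min(d[2], as.integer(round(sqrt(cells_per[i] * aspect)))))
      h <- max(1L, min(d[1], as.integer(round(cells_per[i] / w))))
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        r0 <- sample.int(d[1] - h + 1L, 1)
        c0 <- sample.int(d[2] - w + 1L, 1)
        rr <- r0:(r0 + h - 1L); cc <- c0:(c0 + w - 1L)
        if (!any(occ[rr, cc])) {
          occ[rr, cc] <- TRUE
          ## rectangle corners in km; rows count from the north edge
          x0 <- stack$origin[1] + (c0 - 1L) * stack$cell_km
          x1 <- stack$origin[1] + (c0 + w - 1L) * stack$cell_km
          y1 <- stack$origin[2] + (d[1] - r0 + 1L) * stack$cell_km
          y0 <- stack$origin[2] + (d[1] - (r0 + h - 1L)) * stack$cell_km
          polys[[i]] <- list(id = sprintf("PA_%02d", i),
                             coords = data.frame(x = c(x0, x1, x1, x0),
                                                 y = c(y0, y0, y1, y1)))
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(sprintf(
          "infeasible packing: could not place polygon %d of %d at fraction %.2f",
          i, n_pas, total_fraction))
      }
    }
    achieved <- sum(occ) / n_cells
    if (abs(achieved - total_fraction) > 0.05) {
      stop(sprintf("packing achieved fraction %.3f outside the %.2f +/- 0.05 contract",
                   achieved, total_fraction))
    }
    class(polys) <- "pa_polygons"
    polys
  })
}
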