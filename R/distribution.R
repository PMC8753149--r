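#' Spatially thin occurrence records
#'
#' Removes clustered records so that no retained pair lies closer than
#' `min_distance` (Euclidean, km). The retained set is chosen greedily over
#' `restarts` random orderings, keeping the ordering that retains the most
#' points; deterministic given `seed`.
#'
#' @param occurrences an [occurrence_set()].
#' @param min_distance minimum pairwise distance, km (0 returns the input).
#' @param seed integer seed.
#' @param restarts number of random greedy orderings tried.
#' @return A thinned `occurrence_set`.
#' @export
spatial_thin <- function(occurrences, min_distance, seed = 1L, restarts = 25L) {
  if (min_distance < 0) stop("min_distance must be >= 0")
  n <- nrow(occurrences)
  if (n == 0 || min_distance == 0) return(occurrences)
  dmat <- as.matrix(stats::dist(cbind(occurrences$x, occurrences$y)))
  best <- integer(0)
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      ord <- sample.int(n)
      keep <- integer(0)
      for (i in ord) {
        if (!length(keep) || all(dmat[i, keep] >= min_distance)) keep <- c(keep, i)
      }
      if (length(keep) > length(best)) best <- keep
    }
  })
  out <- occurrences[sort(best), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Prune highly correlated climate predictors
#'
#' Computes pairwise Spearman rank correlations on a random sample of cells
#' and repeatedly drops the layer with the most above-threshold partners
#' (ties: larger mean absolute correlation, then first in alphabetical
#' order) until no retained pair exceeds the threshold.
#'
#' @param stack a `landscape_stack`.
#' @param layers climate layer names to consider (default all).
#' @param threshold absolute Spearman correlation above which a pair is
#'   considered redundant; in (0, 1].
#' @param sample_n number of cells sampled (>= 10).
#' @param seed integer seed for the cell sample.
#' @return Character vector of retained layer names.
#' @export
prune_correlated_predictors <- function(stack, layers = names(stack$climate),
                                        threshold = 0.8, sample_n = 1000L,
                                        seed = 1L) {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  if (length(layers) < 2) stop("at least two layers are required")
  if (sample_n < 10) stop("sample_n must be >= 10")
  bad <- setdiff(layers, names(stack$climate))
  if (length(bad)) stop("unknown climate layers: ", paste(bad, collapse = ", "))
  n_cells <- prod(grid_dim(stack))
  idx <- with_seed(seed, sample.int(n_cells, min(sample_n, n_cells)))
  vals <- vapply(layers, function(l) stack$climate[[l]][idx],
                 numeric(length(idx)))
  rho <- stats::cor(vals, method = "spearman")
  keep <- layers
  repeat {
    sub <- abs(rho[keep, keep, drop = FALSE])
    diag(sub) <- 0
    n_over <- rowSums(sub > threshold)
    if (all(n_over == 0)) break
    mean_abs <- rowMeans(sub)
    ord <- order(-n_over, -mean_abs, keep)
    keep <- setdiff(keep, keep[ord[1]])
  }
  ## preserve the input layer order in the result
  layers[layers %in% keep]
}

#' Fit the climate-envelope reference suitability model
#'
#' A deliberately simple, monotone presence-envelope model: for each layer
#' the score is 1 when the cell value lies between the presences' lower and
#' upper percentiles (5th-95th by default) and decays linearly with the
#' distance outside the envelope, reaching 0 one envelope-width away;
#' suitability is the product across layers. Any externally produced
#' continuous suitability surface can be substituted downstream.
#'
#' @param occurrences a thinned [occurrence_set()].
#' @param stack a `landscape_stack`.
#' @param layers climate layer names to use.
#' @param percentiles lower/upper envelope percentiles.
#' @param min_occurrences minimum occurrences required to fit (default 20);
#'   species below it are rejected with a condition of class
#'   `min_occurrences_error` so callers can skip them.
#' @return A `suitability_raster`: matrix in `[0, 1]` with attributes
#'   `species` and `model`.
#' @export
fit_envelope_model <- function(occurrences, stack, layers = names(stack$climate),
                               percentiles = c(0.05, 0.95),
                               min_occurrences = 20L) {
  n <- nrow(occurrences)
  if (n < min_occurrences) {
    stop(structure(class = c("min_occurrences_error", "error", "condition"),
                   list(message = sprintf(
                     "species %s: %d occurrences after thinning < required %d",
                     occurrences$species[1] %||% "?", n, min_occurrences),
                     call = sys.call())))
  }
  cells <- xy_cell(stack, occurrences$x, occurrences$y)
  if (anyNA(cells)) stop("occurrences fall outside the grid extent")
  d <- grid_dim(stack)
  suit <- matrix(1, d[1], d[2])
  for (l in layers) {
    v <- stack$climate[[l]]
    pv <- v[cells]
    q <- stats::quantile(pv, percentiles, type = 7, names = FALSE)
    width <- q[2] - q[1]
    if (width <= 0) width <- max(stats::sd(v), 1e-9)
    out_lo <- pmax(0, q[1] - v)
    out_hi <- pmax(0, v - q[2])
    suit <- suit * pmax(0, 1 - (out_lo + out_hi) / width)
  }
  structure(suit, species = occurrences$species[1], model = "envelope",
            class = c("suitability_raster", class(suit)))
}

#' Binarize suitability at the minimum training presence threshold
#'
#' The threshold is the smallest suitability at any training occurrence;
#' cells with suitability greater than or equal to it (inclusive) become 1.
#' Every training presence is therefore retained: zero training omission.
#'
#' @param suitability a `suitability_raster` (values in `[0, 1]`).
#' @param occurrences the training [occurrence_set()].
#' @param stack the `landscape_stack` defining cell geometry.
#' @return A `potential_distribution`: 0/1 matrix with attributes `species`
#'   and `threshold`.
#' @export
threshold_mtp <- function(suitability, occurrences, stack) {
  cells <- xy_cell(stack, occurrences$x, occurrences$y)
  if (anyNA(cells)) stop("occurrences fall outside the grid extent")
  vals <- suitability[cells]
  if (anyNA(vals)) {
    bad <- which(is.na(vals))
    stop("occurrence(s) on no-data cells at rows: ", paste(bad, collapse = ", "))
  }
  thr <- min(vals)
  bin <- matrix(0L, nrow(suitability), ncol(suitability))
  bin[!is.na(suitability) & suitability >= thr] <- 1L
  bin[is.na(suitability)] <- NA_integer_
  structure(bin, species = attr(suitability, "species"), threshold = thr,
            class = c("potential_distribution", class(bin)))
}

#' Clip a potential distribution by species elevation limits
#'
#' Cells with elevation outside `[elev_min_m, elev_max_m]` (inclusive
#' bounds) are set to 0.
#'
#' @param dist a `potential_distribution`.
#' @param elevation elevation matrix (m) on the same grid.
#' @param profile a [species_profile()] carrying the limits.
#' @return The clipped `potential_distribution`.
#' @export
clip_by_elevation <- function(dist, elevation, profile) {
  out <- dist
  outside <- elevation < profile$elev_min_m | elevation > profile$elev_max_m
  out[outside & !is.na(out)] <- 0L
  if (sum(out, na.rm = TRUE) == 0) {
    warning(sprintf("species %s: distribution empty after elevation clipping",
                    profile$species))
  }
  out
}
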