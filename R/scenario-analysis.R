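#' Percent of a connectivity area inside a zone
#'
#' `100 * |connectivity cells inside the zone| / |connectivity cells|`,
#' with polygon zones rasterized by the cell-centre rule.
#'
#' @param conn logical connectivity-area matrix.
#' @param zone logical matrix on the same grid, or a `pa_polygons` set
#'   (then `stack` is required for rasterization).
#' @param stack optional `landscape_stack` for polygon zones.
#' @return Percentage in `[0, 100]`; `NA` (with a warning) when the
#'   connectivity area is empty.
#' @export
overlap_percent <- function(conn, zone, stack = NULL) {
  if (inherits(zone, "pa_polygons")) {
    if (is.null(zone) || is.null(stack)) stop("polygon zones require the stack")
    zone <- rasterize_polygons(zone, stack)
  }
  n <- sum(conn, na.rm = TRUE)
  if (n == 0) {
    warning("empty connectivity area; overlap undefined")
    return(NA_real_)
  }
  100 * sum(conn & zone, na.rm = TRUE) / n
}

#' PES-potential mask
#'
#' Any cell carrying at least `min_services` overlapping ecosystem services
#' (default 1) is eligible for payment-for-ecosystem-services schemes.
#'
#' @param service_count integer matrix of service counts (0-4).
#' @param min_services inclusive minimum count.
#' @return Logical matrix.
#' @export
pes_potential_mask <- function(service_count, min_services = 1L) {
  !is.na(service_count) & service_count >= min_services
}

#' Randomly allocate PES pixels within hotspots
#'
#' Samples `ceiling(target_area / cell_km^2)` hotspot cells uniformly
#' without replacement, matching a prescribed conservation area.
#'
#' @param hotspot_mask logical matrix of allocatable cells.
#' @param target_area_km2 area to allocate (km^2).
#' @param cell_km cell edge length (km).
#' @param seed integer seed.
#' @return Logical matrix of allocated cells.
#' @export
random_pes_allocation <- function(hotspot_mask, target_area_km2, cell_km = 1,
                                  seed = 1L) {
  cells <- which(hotspot_mask)
  k <- as.integer(ceiling(target_area_km2 / cell_km^2))
  if (k > length(cells)) {
    stop(sprintf(
      "hotspot area (%.4g km^2) short of target by %.4g km^2",
      length(cells) * cell_km^2, target_area_km2 - length(cells) * cell_km^2))
  }
  take <- with_seed(seed, sample(cells, k))
  out <- matrix(FALSE, nrow(hotspot_mask), ncol(hotspot_mask))
  out[take] <- TRUE
  out
}

#' Summarize a per-species metric across the assemblage
#'
#' @param values numeric vector (one value per species); NAs dropped.
#' @return List: mean, sd (sample, n-1; 0 with `sd_defined = FALSE` for a
#'   single species), min, max, n.
#' @export
summarize_assemblage <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("at least one species value is required")
  list(mean = mean(v),
       sd = if (length(v) > 1) stats::sd(v) else 0,
       sd_defined = length(v) > 1,
       min = min(v), max = max(v), n = length(v))
}

#' Area-matched comparison of new protected areas versus PES
#'
#' For each species: the baseline is the percent of its connectivity area
#' inside existing protected areas; the new-PA scenario adds the proposed
#' protected areas; the PES scenario adds, instead, a random allocation of
#' hotspot pixels matching the proposed-PA area, averaged over replicates
#' (each replicate's allocation is shared across species, since all share
#' one landscape). Net gains are scenario minus baseline.
#'
#' @param conn_masks named list of per-species logical connectivity masks.
#' @param existing_pa logical matrix (or `pa_polygons` with `stack`).
#' @param proposed_pa logical matrix (or `pa_polygons` with `stack`).
#' @param hotspot_mask logical matrix of PES-allocatable cells.
#' @param cell_km cell edge length (km).
#' @param replicates number of random PES allocations (default 100).
#' @param seed master seed; per-replicate seeds derive from it.
#' @param stack optional `landscape_stack` for polygon zones.
#' @return A `scenario_result` list: `species` (data frame of per-species
#'   percentages and gains), `summary` (per-metric assemblage summaries),
#'   `replicates`, `target_area_km2`.
#' @export
compare_pa_vs_pes <- function(conn_masks, existing_pa, proposed_pa,
                              hotspot_mask, cell_km = 1, replicates = 100L,
                              seed = 1L, stack = NULL) {
  if (replicates < 1) stop("replicates must be >= 1")
  rast <- function(z) {
    if (inherits(z, "pa_polygons")) rasterize_polygons(z, stack) else z
  }
  existing_pa <- rast(existing_pa); proposed_pa <- rast(proposed_pa)
  target_area <- sum(proposed_pa, na.rm = TRUE) * cell_km^2
  allocs <- lapply(seq_len(replicates), function(r) {
    random_pes_allocation(hotspot_mask, target_area, cell_km,
                          seed = derive_seed(seed, r))
  })
  pes_mask <- pes_potential_mask_from(hotspot_mask)
  rows <- lapply(names(conn_masks), function(sp) {
    conn <- conn_masks[[sp]]
    area <- sum(conn, na.rm = TRUE) * cell_km^2
    base <- overlap_percent(conn, existing_pa)
    newpa <- overlap_percent(conn, existing_pa | proposed_pa)
    pes_pot <- overlap_percent(conn, pes_mask)
    pes_only <- overlap_percent(conn, pes_mask & !existing_pa)
    neither <- 100 - base - pes_only
    reps <- vapply(allocs, function(al) {
      overlap_percent(conn, existing_pa | al)
    }, numeric(1))
    data.frame(species = sp, conn_area_km2 = area,
               pct_pa = base, pct_pes_potential = pes_pot,
               pct_pes_only = pes_only, pct_neither = neither,
               pct_newpa = newpa,
               pct_pes_mean = mean(reps), pct_pes_sd = stats::sd(reps),
               gain_newpa = newpa - base, gain_pes = mean(reps) - base)
  })
  species <- do.call(rbind, rows)
  rownames(species) <- NULL
  metrics <- c("pct_pa", "pct_pes_potential", "pct_neither", "pct_newpa",
               "pct_pes_mean", "gain_newpa", "gain_pes")
  summary <- lapply(stats::setNames(metrics, metrics), function(m) {
    summarize_assemblage(species[[m]])
  })
  structure(list(species = species, summary = summary,
                 replicates = replicates, target_area_km2 = target_area),
            class = "scenario_result")
}

## the hotspot mask already is the PES-potential layer in most runs; keep a
## single point of truth for the "mask as logical" coercion.
pes_potential_mask_from <- function(m) !is.na(m) & m

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %d species, %d PES replicates, target area %.4g km^2\n",
              nrow(x$species), x$replicates, x$target_area_km2))
  cat(sprintf("  PA baseline %.1f%% -> new-PA %.1f%% (gain %.1f) | PES %.1f%% (gain %.1f)\n",
              x$summary$pct_pa$mean, x$summary$pct_newpa$mean,
              x$summary$gain_newpa$mean, x$summary$pct_pes_mean$mean,
              x$summary$gain_pes$mean))
  invisible(x)
}
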