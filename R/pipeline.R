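#' Build and validate a run configuration
#'
#' Collects the per-stage parameters of the full pipeline with documented
#' defaults. All values are echoed into run metadata so outputs are
#' self-describing.
#'
#' @param seed master seed; every stage derives its own seed from it.
#' @param min_occurrences minimum thinned occurrences per modelled species.
#' @param corr_threshold Spearman threshold for predictor pruning.
#' @param corr_sample_n cells sampled for the correlation estimate.
#' @param thin_restarts greedy restarts for spatial thinning.
#' @param connectivity patch connectivity convention (4 or 8).
#' @param up_to_year forest losses up to this year are applied.
#' @param target habitat fraction for connectivity-area selection.
#' @param bc_weighting betweenness weighting ("topological" or "cost").
#' @param barrier resistance barrier mode ("infinite" or "finite").
#' @param replicates PES allocation replicates.
#' @param envelope_percentiles envelope model percentiles.
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed = 1L, min_occurrences = 20L, corr_threshold = 0.8,
                       corr_sample_n = 1000L, thin_restarts = 25L,
                       connectivity = 8, up_to_year = 2016L, target = 0.5,
                       bc_weighting = "topological", barrier = "infinite",
                       replicates = 100L,
                       envelope_percentiles = c(0.05, 0.95)) {
  cfg <- list(seed = as.integer(seed), min_occurrences = min_occurrences,
              corr_threshold = corr_threshold, corr_sample_n = corr_sample_n,
              thin_restarts = thin_restarts, connectivity = connectivity,
              up_to_year = up_to_year, target = target,
              bc_weighting = bc_weighting, barrier = barrier,
              replicates = replicates,
              envelope_percentiles = envelope_percentiles)
  if (!cfg$connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  if (cfg$target <= 0 || cfg$target > 1) stop("target must lie in (0, 1]")
  if (cfg$corr_threshold <= 0 || cfg$corr_threshold > 1) {
    stop("corr_threshold must lie in (0, 1]")
  }
  if (cfg$replicates < 1) stop("replicates must be >= 1")
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the full per-species pipeline
#'
#' Executes, in order: spatial thinning, predictor pruning, the suitability
#' model (the built-in climate envelope unless `suitability` is supplied),
#' minimum-training-presence thresholding, elevation clipping, habitat
#' masking, forest-loss update, patch labeling, home-range filtering, patch
#' quality, resistance surface, least-cost distances, the dispersal-bounded
#' patch graph, index computation and ranking, and connectivity-area
#' selection. Species failing the minimum-occurrence rule are skipped, not
#' fatal.
#'
#' @param stack a `landscape_stack`.
#' @param occurrences the species' [occurrence_set()].
#' @param profile a [species_profile()].
#' @param config a [run_config()].
#' @param suitability optional externally produced suitability matrix.
#' @return A `species_run` list of all stage artifacts, or (when skipped) a
#'   list with `skipped = TRUE` and a `reason`.
#' @export
run_species <- function(stack, occurrences, profile, config = run_config(),
                        suitability = NULL) {
  sp <- profile$species
  thinned <- spatial_thin(occurrences, profile$thinning_km,
                          seed = derive_seed(config$seed, 1),
                          restarts = config$thin_restarts)
  if (nrow(thinned) < config$min_occurrences) {
    return(structure(list(species = sp, skipped = TRUE,
                          reason = "min_occurrences",
                          n_occurrences = nrow(thinned)),
                     class = "species_run"))
  }
  layers <- prune_correlated_predictors(
    stack, threshold = config$corr_threshold,
    sample_n = config$corr_sample_n, seed = derive_seed(config$seed, 2))
  if (is.null(suitability)) {
    suitability <- fit_envelope_model(
      thinned, stack, layers,
      percentiles = config$envelope_percentiles,
      min_occurrences = config$min_occurrences)
  }
  dist <- threshold_mtp(suitability, thinned, stack)
  dist <- clip_by_elevation(dist, stack$elevation, profile)
  mask0 <- habitat_mask(dist, stack$land_cover, profile, stack$registry)
  mask <- apply_forest_loss(mask0, stack$forest_loss_year, config$up_to_year)
  patches <- label_patches(mask, config$connectivity, stack$cell_km, sp)
  patches <- filter_by_home_range(patches, profile$home_range_median)
  if (!nrow(patches$patches)) {
    return(structure(list(species = sp, skipped = TRUE, reason = "no_habitat",
                          n_occurrences = nrow(thinned)),
                     class = "species_run"))
  }
  patches <- patch_quality(patches, stack$land_cover, stack$registry)
  resistance <- build_resistance(stack, dist, patches, profile,
                                 barrier = config$barrier)
  distances <- least_cost_distances(resistance, patches,
                                    max_cost = profile$dispersal_km)
  graph <- build_graph(patches, distances, profile$dispersal_km)
  index_table <- rescale_and_rank(graph, landscape_area_km2(stack),
                                  bc_weighting = config$bc_weighting)
  areas <- select_connectivity_areas(index_table, target = config$target)
  structure(list(
    species = sp, skipped = FALSE,
    occurrences = thinned, layers = layers, suitability = suitability,
    distribution = dist, habitat_mask = mask, patches = patches,
    resistance = resistance, distances = distances, graph = graph,
    index_table = index_table, connectivity_areas = areas,
    connectivity_mask = connectivity_mask(areas, patches),
    config = config
  ), class = "species_run")
}

#' Run the pipeline for an assemblage and compare conservation scenarios
#'
#' Runs [run_species()] for every profile, then the area-matched
#' protected-area versus PES comparison over the species that succeeded.
#'
#' @param stack a `landscape_stack`.
#' @param occurrences named list of [occurrence_set()]s, one per species.
#' @param profiles named list of [species_profile()]s.
#' @param existing_pa,proposed_pa logical masks or `pa_polygons`.
#' @param hotspot_mask logical matrix of PES-allocatable cells; defaults to
#'   [pes_potential_mask()] of the stack's service counts.
#' @param config a [run_config()].
#' @return An `assemblage_run`: `runs` (per species), `skipped` (reasons),
#'   `scenario` (a `scenario_result`).
#' @export
run_assemblage <- function(stack, occurrences, profiles, existing_pa,
                           proposed_pa, hotspot_mask = NULL,
                           config = run_config()) {
  hotspot_mask <- hotspot_mask %||% pes_potential_mask(stack$service_count)
  runs <- lapply(profiles, function(p) {
    run_species(stack, occurrences[[p$species]], p, config)
  })
  names(runs) <- vapply(profiles, `[[`, character(1), "species")
  ok <- !vapply(runs, `[[`, logical(1), "skipped")
  if (!any(ok)) {
    stop("no species completed the pipeline: ",
         paste(sprintf("%s (%s)", names(runs), vapply(runs, `[[`, character(1), "reason")),
               collapse = "; "))
  }
  conn_masks <- lapply(runs[ok], `[[`, "connectivity_mask")
  scenario <- compare_pa_vs_pes(conn_masks, existing_pa, proposed_pa,
                                hotspot_mask, cell_km = stack$cell_km,
                                replicates = config$replicates,
                                seed = derive_seed(config$seed, 9000),
                                stack = stack)
  structure(list(runs = runs,
                 skipped = lapply(runs[!ok], `[[`, "reason"),
                 scenario = scenario, config = config),
            class = "assemblage_run")
}

#' Write per-species run artifacts
#'
#' Emits the standard text artifacts for one species run: patch table CSV,
#' distance-table CSV, graph node/edge CSVs, index-table CSV, distribution /
#' habitat / connectivity rasters as ASCII grids, and a JSON metadata
#' sidecar echoing the configuration.
#'
#' @param run a non-skipped `species_run`.
#' @param dir output directory (created if needed).
#' @param stack the `landscape_stack` (for grid georeferencing).
#' @return The directory, invisibly.
#' @export
write_species_artifacts <- function(run, dir, stack) {
  if (isTRUE(run$skipped)) stop("cannot write artifacts for a skipped species")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  utils::write.csv(run$patches$patches, p("patches.csv"), row.names = FALSE)
  utils::write.csv(run$distances$table, p("distances.csv"), row.names = FALSE)
  utils::write.csv(run$graph$nodes, p("graph_nodes.csv"), row.names = FALSE)
  utils::write.csv(run$graph$edges, p("graph_edges.csv"), row.names = FALSE)
  utils::write.csv(run$index_table, p("index_table.csv"), row.names = FALSE)
  write_occurrences_csv(run$occurrences, p("occurrences_thinned.csv"))
  wg <- function(m, f) write_ascii_grid(m, p(f), stack$cell_km, stack$origin)
  wg(unclass(run$suitability), "suitability.asc")
  wg(unclass(run$distribution), "distribution.asc")
  wg(run$patches$labels, "patch_labels.asc")
  wg(run$connectivity_mask * 1, "connectivity_areas.asc")
  meta <- c(list(species = run$species,
                 mtp_threshold = attr(run$distribution, "threshold"),
                 layers = run$layers,
                 selected_ids = run$connectivity_areas$selected_ids,
                 selected_area_km2 = run$connectivity_areas$selected_area_km2),
            unclass(run$config))
  jsonlite::write_json(meta, p("metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write assemblage-level scenario results
#'
#' @param assemblage an `assemblage_run`.
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_assemblage_artifacts <- function(assemblage, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(assemblage$scenario$species,
                   file.path(dir, "scenario_species.csv"), row.names = FALSE)
  summ <- do.call(rbind, lapply(names(assemblage$scenario$summary), function(m) {
    s <- assemblage$scenario$summary[[m]]
    data.frame(metric = m, mean = s$mean, sd = s$sd, min = s$min, max = s$max,
               n = s$n)
  }))
  utils::write.csv(summ, file.path(dir, "scenario_summary.csv"), row.names = FALSE)
  jsonlite::write_json(
    c(list(skipped = assemblage$skipped), unclass(assemblage$config)),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
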