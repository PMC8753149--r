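#' Habitat mask from distribution and land cover
#'
#' A cell is habitat iff it lies inside the potential distribution and its
#' land-cover code is one of the species' reported habitat classes.
#'
#' @param dist a `potential_distribution` (0/1 matrix).
#' @param land_cover integer land-cover matrix.
#' @param profile a [species_profile()].
#' @param registry the [cover_registry()] (habitat codes must be present).
#' @return Logical habitat matrix.
#' @export
habitat_mask <- function(dist, land_cover, profile,
                         registry = default_cover_registry()) {
  if (!length(profile$habitat_classes)) stop("profile has no habitat classes")
  bad <- setdiff(profile$habitat_classes, registry$code)
  if (length(bad)) {
    stop("habitat class code(s) absent from registry: ", paste(bad, collapse = ", "))
  }
  inside <- !is.na(dist) & dist == 1
  inside & matrix(land_cover %in% profile$habitat_classes, nrow(dist), ncol(dist))
}

#' Remove forest-loss cells from a habitat mask
#'
#' Cells whose recorded loss year is less than or equal to `up_to_year` are
#' removed; all others are untouched.
#'
#' @param mask logical habitat matrix.
#' @param loss_year integer loss-year matrix (NA = no loss).
#' @param up_to_year losses up to and including this year are applied.
#' @return Updated logical matrix.
#' @export
apply_forest_loss <- function(mask, loss_year, up_to_year) {
  lost <- !is.na(loss_year) & loss_year <= up_to_year
  mask & !lost
}

#' Label habitat patches as connected components
#'
#' Maximal connected components of the mask under 8-neighbour (default) or
#' 4-neighbour adjacency, by breadth-first flood fill. Patch areas are cell
#' counts times the cell area.
#'
#' @param mask logical (or 0/1) habitat matrix.
#' @param connectivity 4 or 8 (8 joins diagonal-touching cells).
#' @param cell_km cell edge length, km.
#' @param species species id carried through to downstream tables.
#' @return A `patch_set`: list with `labels` (integer matrix, 0 =
#'   background), `patches` (data frame id, ncells, area_km2), `cells`
#'   (list of cell-index vectors), `cell_km`, `connectivity`, `species`.
#' @export
label_patches <- function(mask, connectivity = 8, cell_km = 1,
                          species = "species_1") {
  d <- dim(mask)
  m <- !is.na(mask) & mask > 0
  lab <- matrix(0L, d[1], d[2])
  nextid <- 0L
  cells <- list()
  queue <- integer(prod(d))
  for (start in which(m & lab == 0L)) {
    if (lab[start] != 0L) next
    nextid <- nextid + 1L
    lab[start] <- nextid
    queue[1L] <- start
    head <- 1L; tail <- 1L
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L
      for (nb in cell_neighbors(cur, d[1], d[2], connectivity)) {
        if (m[nb] && lab[nb] == 0L) {
          lab[nb] <- nextid
          tail <- tail + 1L
          queue[tail] <- nb
        }
      }
    }
  }
  ids <- seq_len(nextid)
  cells <- if (nextid > 0) split(which(lab > 0L), lab[lab > 0L]) else list()
  ncells <- vapply(cells, length, integer(1))
  patches <- data.frame(id = ids, ncells = as.integer(ncells),
                        area_km2 = ncells * cell_km^2)
  structure(list(labels = lab, patches = patches,
                 cells = unname(cells), cell_km = cell_km,
                 connectivity = connectivity, species = species),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %s: %d patches, %.4g km^2 total\n",
              x$species, nrow(x$patches), sum(x$patches$area_km2)))
  invisible(x)
}

#' Filter patches by home-range size
#'
#' Retains patches whose area is greater than or equal to the species'
#' median home range (inclusive bound). Patch ids are kept stable; removed
#' patches become background in the label raster.
#'
#' @param patches a `patch_set`.
#' @param hr_median home-range median (km^2), > 0.
#' @return The filtered `patch_set`.
#' @export
filter_by_home_range <- function(patches, hr_median) {
  if (hr_median <= 0) stop("hr_median must be positive")
  keep <- patches$patches$area_km2 >= hr_median
  out <- patches
  out$patches <- patches$patches[keep, , drop = FALSE]
  rownames(out$patches) <- NULL
  out$cells <- patches$cells[keep]
  dropped <- patches$patches$id[!keep]
  if (length(dropped)) {
    out$labels[out$labels %in% dropped] <- 0L
  }
  if (!nrow(out$patches)) {
    warning(sprintf("species %s: no habitat patch reaches the %.3g km^2 home range",
                    patches$species, hr_median))
  }
  out
}

#' Patch quality and quality-weighted area
#'
#' Quality is the fraction of patch cells whose cover class carries the
#' natural / semi-natural flag (or, in `"binary"` mode, 1 iff any such cell
#' is present); QA is quality times patch area in km^2.
#'
#' @param patches a `patch_set`.
#' @param land_cover integer land-cover matrix.
#' @param registry the [cover_registry()]; must cover all codes present.
#' @param mode `"fraction"` (default) or `"binary"`.
#' @return The `patch_set` with `quality` and `qa_km2` columns added.
#' @export
patch_quality <- function(patches, land_cover, registry = default_cover_registry(),
                          mode = c("fraction", "binary")) {
  mode <- match.arg(mode)
  codes <- unique(land_cover[patches$labels > 0L])
  bad <- setdiff(codes[!is.na(codes)], registry$code)
  if (length(bad)) stop("cover codes absent from registry: ", paste(bad, collapse = ", "))
  natural_codes <- registry$code[registry$natural]
  q <- vapply(patches$cells, function(cc) {
    mean(land_cover[cc] %in% natural_codes)
  }, numeric(1))
  if (mode == "binary") q <- as.numeric(q > 0)
  patches$patches$quality <- q
  patches$patches$qa_km2 <- q * patches$patches$area_km2
  patches
}

#' Forest-loss statistics within habitat
#'
#' Per-year and total loss of habitat area, as km^2 and as a percentage of
#' the initial habitat, over a range of years.
#'
#' @param mask_before logical habitat mask before any loss is applied.
#' @param loss_year integer loss-year matrix (NA = no loss).
#' @param years the year range to tabulate (e.g. `2008:2016`).
#' @param cell_km cell edge length, km.
#' @return List with `per_year` (data frame year, loss_km2, loss_pct),
#'   `total_km2`, `total_pct`, `mean_annual_km2`, `mean_annual_pct`.
#' @export
forest_loss_stats <- function(mask_before, loss_year, years, cell_km = 1) {
  if (!length(years)) stop("years must be nonempty")
  habitat0 <- sum(mask_before, na.rm = TRUE) * cell_km^2
  per_year <- vapply(years, function(y) {
    sum(mask_before & !is.na(loss_year) & loss_year == y, na.rm = TRUE) * cell_km^2
  }, numeric(1))
  pct <- if (habitat0 > 0) 100 * per_year / habitat0 else rep(0, length(years))
  list(
    per_year = data.frame(year = years, loss_km2 = per_year, loss_pct = pct),
    total_km2 = sum(per_year), total_pct = sum(pct),
    mean_annual_km2 = mean(per_year), mean_annual_pct = mean(pct)
  )
}
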