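#' Cover-class registry
#'
#' A registry maps integer land-cover codes to a class name, a natural /
#' semi-natural flag (used for patch quality and the service-count
#' association in the synthetic generator), and a default movement
#' resistance weight (>= 1, in km-equivalents per km traversed).
#'
#' @param code integer class codes (unique).
#' @param name class names.
#' @param natural logical; whether the class is natural or semi-natural.
#' @param resistance default resistance weight per class, all >= 1.
#' @param forest logical; classes whose cells can experience forest loss.
#' @return A `cover_registry` data frame.
#' @export
cover_registry <- function(code, name, natural, resistance, forest = natural & resistance <= 2) {
  if (anyDuplicated(code)) stop("cover class codes must be unique")
  if (any(resistance < 1)) stop("resistance weights must be >= 1")
  reg <- data.frame(code = as.integer(code), name = as.character(name),
                    natural = as.logical(natural), resistance = as.numeric(resistance),
                    forest = as.logical(forest))
  class(reg) <- c("cover_registry", "data.frame")
  reg
}

#' Default cover-class registry used by the synthetic landscape
#'
#' A seven-class mosaic loosely patterned on a tropical land-cover legend:
#' two forest classes, shrubland and wetland (natural / semi-natural), and
#' pasture, cropland and urban (transformed), with increasing resistance.
#'
#' @return A `cover_registry`.
#' @export
default_cover_registry <- function() {
  cover_registry(
    code       = 1:7,
    name       = c("dense_forest", "open_forest", "shrubland", "wetland",
                   "pasture", "cropland", "urban"),
    natural    = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    resistance = c(1, 1, 2, 3, 10, 30, 100),
    forest     = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
}

#' Construct a landscape stack
#'
#' Bundles the aligned raster layers the pipeline consumes: continuous
#' climate predictors, elevation (m), categorical land cover, forest-loss
#' year (NA where no loss) and an ecosystem-service count (0-4), all on one
#' grid. Row 1 is the northern edge; cell centres define point membership.
#'
#' @param climate named list of numeric matrices (arbitrary units).
#' @param elevation numeric matrix, metres above sea level.
#' @param land_cover integer matrix of registry codes.
#' @param forest_loss_year integer matrix (calendar year) or NA for no loss.
#' @param service_count integer matrix with values 0-4.
#' @param cell_km cell edge length in km.
#' @param origin (x, y) of the grid's lower-left corner, km.
#' @param registry a [cover_registry()].
#' @return A `landscape_stack`.
#' @export
landscape_stack <- function(climate, elevation, land_cover, forest_loss_year,
                            service_count, cell_km, origin = c(0, 0),
                            registry = default_cover_registry()) {
  stack <- structure(list(
    climate = climate, elevation = elevation,
    land_cover = land_cover, forest_loss_year = forest_loss_year,
    service_count = service_count, cell_km = as.numeric(cell_km),
    origin = as.numeric(origin), registry = registry
  ), class = "landscape_stack")
  validate_landscape_stack(stack)
  stack
}

#' @export
print.landscape_stack <- function(x, ...) {
  d <- grid_dim(x)
  cat(sprintf("<landscape_stack> %d x %d cells, %.3g km cells, %d climate layers\n",
              d[1], d[2], x$cell_km, length(x$climate)))
  invisible(x)
}

#' Validate a landscape stack's invariants
#'
#' Checks layer alignment, land-cover codes against the registry, the
#' service-count range and that forest loss only occurs on forest classes.
#'
#' @param stack a `landscape_stack`.
#' @return The stack, invisibly; errors on violation.
#' @export
validate_landscape_stack <- function(stack) {
  d <- dim(stack$elevation)
  layers <- c(stack$climate, list(stack$land_cover, stack$forest_loss_year,
                                  stack$service_count))
  for (l in layers) {
    if (!identical(dim(l), d)) stop("all layers must share identical dimensions")
  }
  if (stack$cell_km <= 0) stop("cell_km must be positive")
  codes <- unique(as.vector(stack$land_cover))
  bad <- setdiff(codes[!is.na(codes)], stack$registry$code)
  if (length(bad)) stop("land-cover codes absent from registry: ", paste(bad, collapse = ", "))
  sc <- as.vector(stack$service_count)
  if (any(!is.na(sc) & (sc < 0 | sc > 4))) stop("service_count must lie in 0..4")
  forest_codes <- stack$registry$code[stack$registry$forest]
  lossy <- !is.na(stack$forest_loss_year)
  if (any(lossy & !(stack$land_cover %in% forest_codes))) {
    stop("forest_loss_year set on non-forest cells")
  }
  invisible(stack)
}

#' Grid dimensions (rows, cols) of a landscape stack
#' @param stack a `landscape_stack`.
#' @return Integer vector (rows, cols).
#' @export
grid_dim <- function(stack) dim(stack$elevation)

#' Landscape area in square kilometres
#' @param stack a `landscape_stack`.
#' @return Total grid area (km^2).
#' @export
landscape_area_km2 <- function(stack) prod(grid_dim(stack)) * stack$cell_km^2

## Cell centre coordinates (km) for column-major cell indices.
cell_xy <- function(stack, idx) {
  nr <- grid_dim(stack)[1]
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  cbind(x = stack$origin[1] + (c - 0.5) * stack$cell_km,
        y = stack$origin[2] + (nr - r + 0.5) * stack$cell_km)
}

## Column-major cell index containing each (x, y) point; NA outside extent.
xy_cell <- function(stack, x, y) {
  d <- grid_dim(stack)
  cc <- floor((x - stack$origin[1]) / stack$cell_km) + 1
  rr <- d[1] - floor((y - stack$origin[2]) / stack$cell_km)
  ok <- cc >= 1 & cc <= d[2] & rr >= 1 & rr <= d[1]
  out <- rep(NA_integer_, length(x))
  out[ok] <- (as.integer(cc[ok]) - 1L) * d[1] + as.integer(rr[ok])
  out
}

#' Occurrence set
#'
#' @param species species identifier.
#' @param x,y point coordinates in the grid's projected km units.
#' @param source optional source tag per point.
#' @return An `occurrence_set` data frame with columns species, x, y (exact
#'   duplicate points removed).
#' @export
occurrence_set <- function(species, x, y, source = NA_character_) {
  df <- data.frame(species = as.character(species), x = as.numeric(x),
                   y = as.numeric(y), source = source)
  df <- df[!duplicated(df[, c("species", "x", "y")]), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("occurrence_set", "data.frame")
  df
}

## Ray-casting point-in-polygon; poly is a data.frame/matrix of x,y vertices
## (ring need not be closed). Boundary points count as inside.
point_in_polygon <- function(px, py, poly) {
  vx <- poly[, 1]; vy <- poly[, 2]
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize polygons onto the stack grid
#'
#' Cell-centre-in-polygon rule: a cell belongs to the zone iff its centre
#' falls inside any polygon.
#'
#' @param polys a `pa_polygons` list (each element has `$coords` with x, y).
#' @param stack a `landscape_stack` supplying the grid.
#' @return Logical matrix on the stack grid.
#' @export
rasterize_polygons <- function(polys, stack) {
  d <- grid_dim(stack)
  idx <- seq_len(prod(d))
  ctr <- cell_xy(stack, idx)
  inside <- logical(length(idx))
  for (p in polys) {
    inside <- inside | point_in_polygon(ctr[, "x"], ctr[, "y"], as.matrix(p$coords))
  }
  matrix(inside, d[1], d[2])
}
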