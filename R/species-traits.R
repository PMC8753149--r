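#' Remove home-range outliers by Tukey fences
#'
#' Retains observations inside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with
#' quartiles computed on the input list by linear interpolation of order
#' statistics (quantile type 7). A single pass of the literal rule: fences
#' are never recomputed on the retained list, so the operation is not
#' guaranteed idempotent.
#'
#' @param observations positive home-range areas (km^2).
#' @return The retained observations, input order preserved.
#' @export
remove_home_range_outliers <- function(observations) {
  if (length(observations) == 0) stop("at least one observation is required")
  if (any(observations <= 0)) stop("home-range observations must be positive")
  q <- stats::quantile(observations, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  observations[observations >= lo & observations <= hi]
}

#' Median home range
#'
#' @param retained nonempty vector of home-range areas (km^2), normally the
#'   output of [remove_home_range_outliers()].
#' @return The standard median (mean of the middle two for even n).
#' @export
median_home_range <- function(retained) {
  if (length(retained) == 0) stop("cannot take the median of an empty list")
  stats::median(retained)
}

#' Dispersal distance from home-range size
#'
#' Applies the isometric (square-root) allometry between dispersal distance
#' and home-range area: `distance = c * sqrt(home_range)`. The default
#' coefficients follow the allometric literature for mammals: c = 7 for
#' median natal dispersal and c = 40 for maximum dispersal. Maximum is the
#' package default for bounding graph links (the conservative choice for
#' reaching distant patches).
#'
#' @param hr_median home-range area (km^2), > 0.
#' @param mode `"maximum"` or `"median"` dispersal.
#' @param coefficient optional override of the allometric coefficient.
#' @return Dispersal distance in km.
#' @export
dispersal_from_home_range <- function(hr_median,
                                      mode = c("maximum", "median"),
                                      coefficient = NULL) {
  if (any(hr_median <= 0)) stop("home-range median must be positive")
  mode <- match.arg(mode)
  c0 <- coefficient %||% switch(mode, maximum = 40, median = 7)
  c0 * sqrt(hr_median)
}

#' Construct a species profile
#'
#' Per-species parameters driving every pipeline stage: habitat cover
#' classes, home-range observations and median, elevation limits, dispersal
#' distance, per-class resistance weights and the occurrence thinning
#' distance.
#'
#' @param species species id.
#' @param habitat_classes integer cover codes the species uses as habitat.
#' @param home_ranges_km2 home-range observations (km^2); may be empty when
#'   `home_range_median` is given directly.
#' @param resistance named numeric vector, cover code -> weight (>= 1).
#' @param elev_min_m,elev_max_m elevation limits (m); default unbounded.
#' @param dispersal_km explicit dispersal distance; when NULL it is derived
#'   allometrically from the home-range median.
#' @param thinning_km occurrence thinning distance; when NULL it defaults to
#'   the home-range diameter `2 * sqrt(median / pi)`.
#' @param dispersal_mode allometry mode when deriving dispersal.
#' @param home_range_median optional precomputed median (km^2).
#' @return A `species_profile` list.
#' @export
species_profile <- function(species, habitat_classes, home_ranges_km2,
                            resistance, elev_min_m = -Inf, elev_max_m = Inf,
                            dispersal_km = NULL, thinning_km = NULL,
                            dispersal_mode = "maximum",
                            home_range_median = NULL) {
  if (is.null(home_range_median)) {
    kept <- remove_home_range_outliers(home_ranges_km2)
    home_range_median <- median_home_range(kept)
  }
  if (home_range_median <= 0) stop("home_range_median must be positive")
  if (elev_min_m > elev_max_m) stop("elev_min_m must not exceed elev_max_m")
  if (is.null(dispersal_km)) {
    dispersal_km <- dispersal_from_home_range(home_range_median, dispersal_mode)
  }
  if (dispersal_km <= 0) stop("dispersal_km must be positive")
  if (is.null(thinning_km)) thinning_km <- 2 * sqrt(home_range_median / pi)
  habitat_classes <- as.integer(habitat_classes)
  if (!length(habitat_classes)) stop("habitat_classes must be nonempty")
  missing_res <- setdiff(as.character(habitat_classes), names(resistance))
  if (length(missing_res)) {
    stop(sprintf("species %s: no resistance entry for habitat class(es) %s",
                 species, paste(missing_res, collapse = ", ")))
  }
  if (any(resistance < 1)) stop("resistance weights must be >= 1")
  structure(list(
    species = as.character(species), habitat_classes = habitat_classes,
    home_ranges_km2 = as.numeric(home_ranges_km2),
    home_range_median = home_range_median,
    elev_min_m = elev_min_m, elev_max_m = elev_max_m,
    dispersal_km = dispersal_km, thinning_km = thinning_km,
    resistance = resistance
  ), class = "species_profile")
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("<species_profile> %s: HR median %.3g km^2, dispersal %.3g km, %d habitat classes\n",
              x$species, x$home_range_median, x$dispersal_km,
              length(x$habitat_classes)))
  invisible(x)
}

#' Load species profiles from trait and resistance tables
#'
#' The trait table is a CSV with columns `species`, `habitat_classes`
#' (semicolon-separated codes), `home_ranges_km2` (semicolon-separated
#' areas) and optionally `elev_min_m`, `elev_max_m`, `dispersal_km`,
#' `thinning_km`. The resistance table is a CSV matrix: one row per species,
#' one column `c<code>` per cover class. Derived fields (median home range,
#' allometric dispersal, thinning distance) are computed when absent;
#' explicit values always win.
#'
#' @param traits_path trait table CSV.
#' @param resistance_path species-by-class resistance CSV.
#' @param dispersal_mode allometry mode for derived dispersal distances.
#' @return A named list of [species_profile()]s.
#' @export
load_species_profiles <- function(traits_path, resistance_path,
                                  dispersal_mode = "maximum") {
  traits <- utils::read.csv(traits_path, stringsAsFactors = FALSE)
  res <- utils::read.csv(resistance_path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  need <- c("species", "habitat_classes", "home_ranges_km2")
  miss <- setdiff(need, names(traits))
  if (length(miss)) stop("trait table lacks column(s): ", paste(miss, collapse = ", "))
  res_codes <- sub("^c", "", setdiff(names(res), "species"))
  split_num <- function(s) as.numeric(strsplit(as.character(s), ";")[[1]])
  opt <- function(row, col) {
    if (!col %in% names(traits)) return(NULL)
    v <- traits[[col]][row]
    if (is.na(v) || identical(v, "")) NULL else as.numeric(v)
  }
  profiles <- lapply(seq_len(nrow(traits)), function(i) {
    sp <- traits$species[i]
    r <- res[res$species == sp, setdiff(names(res), "species"), drop = FALSE]
    if (nrow(r) != 1) stop("resistance table lacks a row for species ", sp)
    rv <- stats::setNames(as.numeric(r[1, ]), res_codes)
    rv <- rv[!is.na(rv)]
    emin <- opt(i, "elev_min_m"); emax <- opt(i, "elev_max_m")
    if (is.null(emin) || is.null(emax)) {
      message("species ", sp, ": elevation limits absent; defaulting to (-Inf, Inf)")
    }
    species_profile(
      species = sp,
      habitat_classes = split_num(traits$habitat_classes[i]),
      home_ranges_km2 = split_num(traits$home_ranges_km2[i]),
      resistance = rv,
      elev_min_m = emin %||% -Inf, elev_max_m = emax %||% Inf,
      dispersal_km = opt(i, "dispersal_km"),
      thinning_km = opt(i, "thinning_km"),
      dispersal_mode = dispersal_mode
    )
  })
  stats::setNames(profiles, traits$species)
}
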