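#' Write a raster layer as an Esri ASCII grid
#'
#' Plain-text single-band raster interchange: a six-line header followed by
#' the cell values row by row from the northern edge, which matches the
#' package's row-1-is-north matrix convention.
#'
#' @param mat numeric matrix (row 1 = north).
#' @param path output file.
#' @param cell_km cell size (km).
#' @param origin lower-left corner (x, y) in km.
#' @param nodata value written for NA cells.
#' @export
write_ascii_grid <- function(mat, path, cell_km = 1, origin = c(0, 0),
                             nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(mat)),
    sprintf("nrows %d", nrow(mat)),
    sprintf("xllcorner %.10g", origin[1]),
    sprintf("yllcorner %.10g", origin[2]),
    sprintf("cellsize %.10g", cell_km),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  m <- mat
  m[is.na(m)] <- nodata
  writeLines(apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 10),
                                           collapse = " ")), con)
  invisible(path)
}

#' Read an Esri ASCII grid
#'
#' @param path file written by [write_ascii_grid()] or any conforming tool.
#' @return A list with `matrix`, `cell_km`, `origin`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  nc <- val("ncols"); nr <- val("nrows"); nodata <- val("NODATA_value")
  body <- lines[-(1:6)]
  vals <- as.numeric(unlist(strsplit(trimws(body), "\\s+")))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  list(matrix = m, cell_km = val("cellsize"),
       origin = c(val("xllcorner"), val("yllcorner")))
}

#' Write occurrences to CSV (species, x, y)
#' @param occ an `occurrence_set`.
#' @param path output file.
#' @export
write_occurrences_csv <- function(occ, path) {
  utils::write.csv(occ[, c("species", "x", "y")], path, row.names = FALSE)
  invisible(path)
}

#' Read occurrences from a species,x,y CSV
#' @param path input file.
#' @return An `occurrence_set`.
#' @export
read_occurrences_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  occurrence_set(df$species, df$x, df$y)
}

#' Write polygons as GeoJSON
#'
#' @param polys a `pa_polygons` list.
#' @param path output file.
#' @export
write_polygons_geojson <- function(polys, path) {
  features <- lapply(polys, function(p) {
    ring <- as.matrix(p$coords)
    if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    list(
      type = "Feature",
      properties = list(id = p$id),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(i) as.numeric(ring[i, ]))))
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons from GeoJSON (Polygon features, outer ring only)
#' @param path input file.
#' @return A `pa_polygons` list.
#' @export
read_polygons_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  polys <- lapply(fc$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(v) as.numeric(unlist(v))))
    list(id = f$properties$id, coords = data.frame(x = ring[, 1], y = ring[, 2]))
  })
  class(polys) <- "pa_polygons"
  polys
}
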