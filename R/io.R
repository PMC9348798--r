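#' Write a raster as an Esri ASCII grid
#'
#' Plain-text raster interchange (cell-center registration, WGS84
#' degrees, north-up rows). NA cells are written as the nodata value.
#'
#' @param raster A [div_raster()].
#' @param path Output file path (conventionally `.asc`).
#' @param nodata Nodata sentinel (default -9999).
#' @export
write_asc_raster <- function(raster, path, nodata = -9999) {
  g <- raster$grid
  step <- grid_step(g)
  hdr <- c(sprintf("ncols %d", g$n_cols),
           sprintf("nrows %d", g$n_rows),
           sprintf("xllcorner %.10g", g$lon_min),
           sprintf("yllcorner %.10g", g$lat_min),
           sprintf("cellsize %.10g", step),
           sprintf("NODATA_value %g", nodata))
  v <- raster$values
  v[is.na(v)] <- nodata
  lines <- apply(v, 1, function(r) paste(format(r, trim = TRUE), collapse = " "))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read an Esri ASCII grid raster
#'
#' @param path File written by [write_asc_raster()] (or any ASCII grid).
#' @param metric Metric label for the returned raster.
#' @return A [div_raster()] with an all-land grid (the format carries no
#'   mask; nodata cells become NA).
#' @export
read_asc_raster <- function(path, metric = "richness") {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(k) as.numeric(strsplit(trimws(hdr[k]), "\\s+")[[1]][2])
  nc <- as.integer(val(1)); nr <- as.integer(val(2))
  xll <- val(3); yll <- val(4); cs <- val(5); nodata <- val(6)
  v <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  v[v == nodata] <- NA
  g <- grid_spec(cs * 60, lon_min = xll, lon_max = xll + nc * cs,
                 lat_min = yll, lat_max = yll + nr * cs,
                 land_mask = !is.na(v))
  div_raster(g, v, metric)
}

#' Write polygons as GeoJSON
#'
#' @param polys A [geo_polygon()] or list of them.
#' @param path Output path.
#' @export
write_geojson <- function(polys, path) {
  if (inherits(polys, "geo_polygon")) polys <- list(polys)
  features <- lapply(seq_along(polys), function(i) {
    rings <- lapply(polys[[i]]$rings, function(r) {
      closed <- rbind(r, r[1, ])
      lapply(seq_len(nrow(closed)), function(k) c(closed[k, 1], closed[k, 2]))
    })
    list(type = "Feature",
         properties = list(id = i),
         geometry = list(type = "Polygon", coordinates = rings))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read GeoJSON polygons
#'
#' Supports Polygon and MultiPolygon features; every ring becomes a ring
#' of one [geo_polygon()] per feature.
#'
#' @param path GeoJSON file path.
#' @return List of [geo_polygon()] objects.
#' @export
read_geojson <- function(path) {
  j <- jsonlite::read_json(path)
  feats <- if (identical(j$type, "FeatureCollection")) j$features else list(j)
  lapply(feats, function(f) {
    geom <- if (!is.null(f$geometry)) f$geometry else f
    ring_mat <- function(rg)
      do.call(rbind, lapply(rg, function(p) c(p[[1]], p[[2]])))
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ring_mat),
      MultiPolygon = unlist(lapply(geom$coordinates,
                                   function(pg) lapply(pg, ring_mat)),
                            recursive = FALSE),
      stop("unsupported geometry type: ", geom$type))
    geo_polygon(rings)
  })
}

#' Write an occurrence table as CSV
#'
#' @param records Occurrence data frame.
#' @param path Output path.
#' @export
write_occurrences_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read an occurrence table from CSV
#'
#' @param path CSV path written by [write_occurrences_csv()].
#' @return Data frame.
#' @export
read_occurrences_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
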