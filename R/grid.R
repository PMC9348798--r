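#' Define a geographic grid
#'
#' A `grid_spec` describes a regular longitude/latitude raster grid
#' (WGS84, north-up, cell-center registration) together with a land mask
#' and an exclusion mask (cells, such as a polar analogue of Antarctica,
#' that are kept out of diversity-center and correlation calculations).
#'
#' @param resolution_arcmin Cell size in arc minutes (60 = 1 degree).
#' @param lon_min,lon_max,lat_min,lat_max Grid extent in degrees. The
#'   extent must be an integer number of cells at the given resolution.
#' @param land_mask Logical matrix (`n_rows x n_cols`, row 1 = northern
#'   edge); `TRUE` for land. Defaults to all-land.
#' @param exclusion_mask Logical matrix flagging cells excluded from
#'   center detection and cross-taxon comparisons. Defaults to none.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(resolution_arcmin, lon_min = -180, lon_max = 180,
                      lat_min = -60, lat_max = 60,
                      land_mask = NULL, exclusion_mask = NULL) {
  if (!is.numeric(resolution_arcmin) || resolution_arcmin <= 0)
    stop("resolution_arcmin must be a positive number")
  if (lon_max <= lon_min || lat_max <= lat_min)
    stop("degenerate grid extent")
  step <- resolution_arcmin / 60
  nc <- (lon_max - lon_min) / step
  nr <- (lat_max - lat_min) / step
  if (abs(nc - round(nc)) > 1e-8 || abs(nr - round(nr)) > 1e-8)
    stop("grid extent is not an integer number of cells at this resolution")
  nc <- as.integer(round(nc))
  nr <- as.integer(round(nr))
  if (nc < 1 || nr < 1) stop("degenerate grid: zero cells")
  if (is.null(land_mask)) land_mask <- matrix(TRUE, nr, nc)
  if (is.null(exclusion_mask)) exclusion_mask <- matrix(FALSE, nr, nc)
  if (!identical(dim(land_mask), as.integer(c(nr, nc))))
    stop("land_mask has wrong shape")
  if (!identical(dim(exclusion_mask), as.integer(c(nr, nc))))
    stop("exclusion_mask has wrong shape")
  structure(list(resolution_arcmin = resolution_arcmin,
                 lon_min = lon_min, lon_max = lon_max,
                 lat_min = lat_min, lat_max = lat_max,
                 n_rows = nr, n_cols = nc,
                 land_mask = land_mask, exclusion_mask = exclusion_mask),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells at %g arcmin, lon [%g, %g], lat [%g, %g]\n",
              x$n_rows, x$n_cols, x$resolution_arcmin,
              x$lon_min, x$lon_max, x$lat_min, x$lat_max))
  cat(sprintf("  land cells: %d, excluded cells: %d\n",
              sum(x$land_mask), sum(x$exclusion_mask)))
  invisible(x)
}

grid_step <- function(grid) grid$resolution_arcmin / 60

#' Cell-center coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return List with `lon` (length `n_cols`) and `lat` (length `n_rows`,
#'   decreasing: row 1 is the northern edge).
#' @export
cell_centers <- function(grid) {
  step <- grid_step(grid)
  list(lon = grid$lon_min + (seq_len(grid$n_cols) - 0.5) * step,
       lat = grid$lat_max - (seq_len(grid$n_rows) - 0.5) * step)
}

#' Map coordinates to grid cells
#'
#' Cells are half-open intervals `[edge, edge + step)` in both axes, so
#' every in-extent coordinate maps to exactly one cell; coordinates on
#' the extreme east/south edges map to the last cell.
#'
#' @param grid A [grid_spec()].
#' @param lon,lat Numeric vectors of coordinates (degrees).
#' @return Data frame with columns `row`, `col` (NA outside the extent).
#' @export
cell_at <- function(grid, lon, lat) {
  step <- grid_step(grid)
  col <- floor((lon - grid$lon_min) / step) + 1
  row <- floor((grid$lat_max - lat) / step) + 1
  col[lon == grid$lon_max] <- grid$n_cols
  row[lat == grid$lat_min] <- grid$n_rows
  bad <- is.na(lon) | is.na(lat) |
    col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

cell_index <- function(grid, row, col) (col - 1L) * grid$n_rows + row

#' Spherical cell areas
#'
#' Analytic area of each grid cell on a sphere of radius 6371 km:
#' `R^2 * d_lambda * (sin(phi_top) - sin(phi_bottom))`. Areas depend only
#' on the latitude band, which makes reprojection to an equal-area CRS
#' unnecessary for any area bookkeeping in the package.
#'
#' @param grid A [grid_spec()].
#' @return Matrix of cell areas in km^2 (`n_rows x n_cols`).
#' @export
spherical_cell_areas <- function(grid) {
  step <- grid_step(grid)
  lat_top <- grid$lat_max - (seq_len(grid$n_rows) - 1) * step
  lat_bot <- lat_top - step
  dl <- step * pi / 180
  band <- EARTH_RADIUS_KM^2 * dl *
    (sin(lat_top * pi / 180) - sin(lat_bot * pi / 180))
  matrix(band, nrow = grid$n_rows, ncol = grid$n_cols)
}

#' Construct a diversity raster
#'
#' Container for a gridded diversity surface (richness, rarity, or any
#' per-cell metric). Values are NA exactly on masked (non-land) cells.
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix `n_rows x n_cols`.
#' @param metric Short label, e.g. `"richness"` or `"rarity"`.
#' @return Object of class `div_raster`.
#' @export
div_raster <- function(grid, values, metric = "richness") {
  stopifnot(inherits(grid, "grid_spec"))
  if (!identical(dim(values), as.integer(c(grid$n_rows, grid$n_cols))))
    stop("values matrix does not match the grid")
  structure(list(grid = grid, values = values, metric = metric),
            class = "div_raster")
}

#' @export
print.div_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<div_raster> metric=%s, %d x %d, %d non-NA cells, range [%g, %g]\n",
              x$metric, x$grid$n_rows, x$grid$n_cols, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$resolution_arcmin, b$resolution_arcmin)) &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(c(a$lon_min, a$lon_max, a$lat_min, a$lat_max),
                     c(b$lon_min, b$lon_max, b$lat_min, b$lat_max)))
}

#' Coarsen a raster by block maximum
#'
#' Aggregates `factor x factor` cell blocks to their maximum value
#' (NA-ignoring; an all-NA block stays NA). A block holding suitability
#' 0.2, 0.45, 0.9, 0.1 coarsens to 0.9 (and a binary 0,0,1,0 block to 1),
#' so any suitable area inside a coarse cell keeps that cell suitable.
#' Grids whose dimensions are not a multiple of `factor` are padded with
#' NA on the south/east edges.
#'
#' @param raster A [div_raster()].
#' @param factor Integer aggregation factor (>= 2; 1 returns the input
#'   unchanged with a warning).
#' @return A [div_raster()] on the coarsened grid.
#' @export
coarsen_max <- function(raster, factor) {
  stopifnot(inherits(raster, "div_raster"))
  factor <- as.integer(factor)
  if (factor < 2) {
    warning("factor < 2: returning the raster unchanged")
    return(raster)
  }
  g <- raster$grid
  nr2 <- ceiling(g$n_rows / factor)
  nc2 <- ceiling(g$n_cols / factor)
  pad <- function(m, fill) {
    out <- matrix(fill, nr2 * factor, nc2 * factor)
    out[seq_len(g$n_rows), seq_len(g$n_cols)] <- m
    out
  }
  v <- pad(raster$values, NA_real_)
  land <- pad(g$land_mask, FALSE)
  excl <- pad(g$exclusion_mask, FALSE)
  block_stat <- function(m, f) {
    # rows of the result index blocks; vapply over block grid
    out <- matrix(NA, nr2, nc2)
    for (i in seq_len(nr2)) {
      ri <- ((i - 1) * factor + 1):(i * factor)
      sub <- m[ri, , drop = FALSE]
      for (j in seq_len(nc2)) {
        cj <- ((j - 1) * factor + 1):(j * factor)
        out[i, j] <- f(sub[, cj])
      }
    }
    out
  }
  vmax <- block_stat(v, function(b) if (all(is.na(b))) NA_real_ else max(b, na.rm = TRUE))
  step <- grid_step(g)
  g2 <- grid_spec(g$resolution_arcmin * factor,
                  lon_min = g$lon_min, lon_max = g$lon_min + nc2 * factor * step,
                  lat_min = g$lat_max - nr2 * factor * step, lat_max = g$lat_max,
                  land_mask = block_stat(land, any),
                  exclusion_mask = block_stat(excl, any))
  div_raster(g2, vmax, raster$metric)
}
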