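#' Choose the range-estimation method for a species
#'
#' Method triage by the count of unique occurrence localities: fewer
#' than 3 localities gives 30-km buffered points, 3-4 an alpha hull
#' polygon, and 5 or more a suitability model predicted inside the
#' buffered alpha hull.
#'
#' @param n_unique_localities Positive integer.
#' @param alpha Alpha-hull parameter in degrees (default 15).
#' @param buffer_km Buffer distance (default 30 km).
#' @return List of class `range_method` with fields `method` (one of
#'   `"buffered_points"`, `"alpha_hull"`, `"sdm_in_hull"`), `alpha`,
#'   `buffer_km`.
#' @export
select_range_method <- function(n_unique_localities, alpha = 15,
                                buffer_km = 30) {
  if (!is.numeric(n_unique_localities) || n_unique_localities < 1 ||
      n_unique_localities != round(n_unique_localities))
    stop("n_unique_localities must be a positive integer")
  method <- if (n_unique_localities < 3) "buffered_points"
            else if (n_unique_localities < 5) "alpha_hull"
            else "sdm_in_hull"
  structure(list(method = method, alpha = alpha, buffer_km = buffer_km),
            class = "range_method")
}

#' Spatially thin occurrence points
#'
#' Subsamples points so that all pairwise great-circle distances among
#' the retained set are at least `min_km`, keeping as many points as
#' possible. Runs `n_rep` seeded randomized greedy passes (random
#' insertion order, keep a point iff it is far enough from everything
#' already kept) and returns the largest retained set; thinning an
#' already-thinned set is a no-op.
#'
#' @param points `n x 2` matrix or data frame of (lon, lat).
#' @param min_km Minimum nearest-neighbor distance (> 0; the pipeline
#'   default is 10 km).
#' @param seed Integer seed making the randomized passes deterministic.
#' @param n_rep Number of greedy passes (default 20).
#' @return Matrix of retained points (a subset of the input rows).
#' @export
thin_points <- function(points, min_km, seed = 1, n_rep = 20) {
  if (min_km <= 0) stop("min_km must be > 0")
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  if (n <= 1) return(pts)
  d <- geosphere::distm(pts, fun = geosphere::distHaversine) / 1000
  ok <- d >= min_km
  diag(ok) <- TRUE
  if (all(ok)) return(pts)  # nothing closer than min_km
  set.seed(seed)
  best <- integer(0)
  for (rep in seq_len(n_rep)) {
    ord <- sample.int(n)
    kept <- integer(0)
    for (i in ord) {
      if (all(ok[i, kept])) kept <- c(kept, i)
    }
    if (length(kept) > length(best)) best <- kept
  }
  pts[sort(best), , drop = FALSE]
}

#' Rasterize a range polygon to a weight raster
#'
#' A cell belongs to the range iff its center lies inside the polygon
#' (even-odd rule; cell centers on the WGS84 grid, half-open cell
#' intervals). Included cells receive weight 1, or the value of the
#' supplied continuous weight raster. If the polygon contains no cell
#' center (possible for small ranges on coarse grids) the cell holding
#' the polygon's centroid is used, so a valid polygon never rasterizes
#' to an empty range; a polygon wholly outside the grid yields an empty
#' raster with a warning.
#'
#' @param polygon A [geo_polygon()].
#' @param grid A [grid_spec()].
#' @param weights Optional numeric matrix of per-cell weights
#'   (`n_rows x n_cols`) for continuous (suitability) ranges.
#' @param land_only Restrict the range to land cells (default TRUE).
#' @return List with `cells` (cell indices) and `w` (weights in [0, 1]).
#' @export
rasterize_range <- function(polygon, grid, weights = NULL, land_only = TRUE) {
  stopifnot(inherits(polygon, "geo_polygon"), inherits(grid, "grid_spec"))
  cc <- cell_centers(grid)
  bb <- do.call(rbind, polygon$rings)
  cols <- which(cc$lon >= min(bb[, 1]) - grid_step(grid) &
                  cc$lon <= max(bb[, 1]) + grid_step(grid))
  rows <- which(cc$lat >= min(bb[, 2]) - grid_step(grid) &
                  cc$lat <= max(bb[, 2]) + grid_step(grid))
  if (!length(cols) || !length(rows)) {
    warning("polygon lies outside the grid")
    return(list(cells = integer(0), w = numeric(0)))
  }
  lon <- rep(cc$lon[cols], each = length(rows))
  lat <- rep(cc$lat[rows], times = length(cols))
  inside <- point_in_polygon(polygon, lon, lat)
  cells <- cell_index(grid,
                      row = rep(rows, times = length(cols))[inside],
                      col = rep(cols, each = length(rows))[inside])
  if (!length(cells)) {
    ctr <- geom_center(bb)
    rc <- cell_at(grid, ctr[1], ctr[2])
    if (is.na(rc$row)) {
      warning("polygon lies outside the grid")
      return(list(cells = integer(0), w = numeric(0)))
    }
    cells <- cell_index(grid, rc$row, rc$col)
  }
  if (land_only) {
    on_land <- grid$land_mask[cells]
    if (any(on_land)) cells <- cells[on_land]
  }
  w <- if (is.null(weights)) rep(1, length(cells)) else weights[cells]
  keep <- !is.na(w) & w > 0
  list(cells = cells[keep], w = w[keep])
}

#' Construct a range estimate
#'
#' @param species_id Species identifier.
#' @param method A `range_method` (or its `method` string).
#' @param polygon The range [geo_polygon()].
#' @param cells,w Sparse weight raster from [rasterize_range()].
#' @param grid The [grid_spec()] the weights live on.
#' @param fallback Which alpha-hull fallback fired, if any.
#' @return Object of class `range_estimate` with `area_km2` equal to the
#'   weighted sum of spherical cell areas (`sum(w * area_i)`).
#' @export
range_estimate <- function(species_id, method, polygon, cells, w, grid,
                           fallback = "none") {
  areas <- spherical_cell_areas(grid)
  area <- sum(w * areas[cells])
  if (!is.finite(area) || area <= 0)
    stop("range estimate has non-positive area: ", species_id)
  structure(list(species_id = species_id,
                 method = if (inherits(method, "range_method")) method$method
                          else method,
                 polygon = polygon, cells = cells, w = w,
                 area_km2 = area, fallback = fallback),
            class = "range_estimate")
}

#' Estimate the range of one species from its occurrence points
#'
#' Applies the full triage: unique localities are counted after rounding
#' coordinates to four decimals; species with < 3 localities get 30-km
#' buffered points, species with 3-4 get a 30-km-buffered alpha hull,
#' and species with >= 5 are spatially thinned (10 km) and modeled with
#' the penalized presence-background engine inside their buffered hull,
#' contributing continuous cloglog suitability weights. If model
#' selection returns the polygon fallback (or thinning leaves fewer than
#' 5 points), the buffered hull with weight 1 is used instead.
#'
#' @param species_id Species identifier.
#' @param points `n x 2` matrix of occurrence (lon, lat).
#' @param grid A [grid_spec()].
#' @param env An `env_stack` (required for the SDM branch).
#' @param bias A [make_bias_field()] sampling-density field (used for
#'   bias-matched background sampling); NULL for uniform background.
#' @param seed Integer seed.
#' @param alpha,buffer_km,thin_km Geometry parameters (defaults 15
#'   degrees, 30 km, 10 km).
#' @param sdm_args List of extra arguments passed to [tune_and_select()]
#'   (e.g. smaller candidate grids for quick runs).
#' @return A [range_estimate()].
#' @export
estimate_range <- function(species_id, points, grid, env = NULL, bias = NULL,
                           seed = 1, alpha = 15, buffer_km = 30, thin_km = 10,
                           sdm_args = list()) {
  pts <- unique(round(as.matrix(points)[, 1:2, drop = FALSE], 4))
  method <- select_range_method(nrow(pts), alpha = alpha, buffer_km = buffer_km)
  fallback <- "none"
  if (method$method == "buffered_points") {
    poly <- buffer_geometry(pts, buffer_km)
    rr <- rasterize_range(poly, grid)
    return(range_estimate(species_id, method, poly, rr$cells, rr$w, grid))
  }
  hull <- alpha_hull(pts, alpha = alpha, fallback_buffer_km = buffer_km)
  fallback <- attr(hull, "fallback")
  poly <- if (identical(fallback, "buffered_points")) hull
          else buffer_geometry(hull, buffer_km)
  rr <- rasterize_range(poly, grid)
  if (method$method == "alpha_hull")
    return(range_estimate(species_id, method, poly, rr$cells, rr$w, grid,
                          fallback = fallback))
  # SDM branch: thin, fit, predict inside the buffered hull
  thinned <- thin_points(pts, thin_km, seed = seed)
  if (nrow(thinned) < 5 || is.null(env) || length(rr$cells) < 10) {
    out <- range_estimate(species_id, "alpha_hull", poly, rr$cells, rr$w, grid,
                          fallback = fallback)
    out$note <- "sdm_branch_fell_back_to_polygon"
    return(out)
  }
  env_at <- function(cells) {
    m <- vapply(env$layers, function(l) l[cells], numeric(length(cells)))
    if (is.null(dim(m))) m <- matrix(m, nrow = length(cells))
    colnames(m) <- names(env$layers)
    m
  }
  rc <- cell_at(grid, thinned[, 1], thinned[, 2])
  pres_cells <- cell_index(grid, rc$row, rc$col)
  ok <- !is.na(pres_cells) & pres_cells %in% rr$cells
  pres_cells <- unique(pres_cells[ok])
  if (length(pres_cells) < 5) {
    out <- range_estimate(species_id, "alpha_hull", poly, rr$cells, rr$w, grid,
                          fallback = fallback)
    out$note <- "sdm_branch_fell_back_to_polygon"
    return(out)
  }
  dens <- if (is.null(bias)) NULL else bias$density
  bg_cells <- sample_background_cells(rr$cells, dens, n = 10000,
                                      seed = seed + 1L)
  pres_env <- env_at(pres_cells)
  bg_env <- env_at(bg_cells)
  sel <- do.call(tune_and_select,
                 c(list(pres_env = pres_env, bg_env = bg_env,
                        seed = seed + 2L), sdm_args))
  if (inherits(sel, "polygon_fallback")) {
    out <- range_estimate(species_id, "alpha_hull", poly, rr$cells, rr$w, grid,
                          fallback = fallback)
    out$note <- "sdm_no_candidate_survived"
    return(out)
  }
  suit <- predict_cloglog(sel$model, env_at(rr$cells))
  out <- range_estimate(species_id, method, poly, rr$cells, suit, grid,
                        fallback = fallback)
  out$model <- sel
  out
}
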