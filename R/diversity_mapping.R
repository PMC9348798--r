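#' Stack range estimates into a species-richness raster
#'
#' Per-cell richness `s_i = sum_j w_ij`: binary (polygonal) ranges
#' contribute 1 where present, modeled ranges their continuous cloglog
#' suitability. Stacking is additive over disjoint species subsets and
#' invariant to species order.
#'
#' @param ranges List of [range_estimate()] objects on `grid`.
#' @param grid A [grid_spec()].
#' @return A [div_raster()] with metric `"richness"` (0 on unoccupied
#'   land, NA on water).
#' @export
stack_richness <- function(ranges, grid) {
  v <- matrix(0, grid$n_rows, grid$n_cols)
  for (r in ranges) {
    stopifnot(inherits(r, "range_estimate"))
    v[r$cells] <- v[r$cells] + r$w
  }
  v[!grid$land_mask] <- NA
  div_raster(grid, v, "richness")
}

#' Rarity (damping) parameters
#'
#' @param c_km2 Constant added to each range area in the rarity weight
#'   `1 / (a_j + c)`. The default 60,000 km^2 (a circle of radius ~138
#'   km) moderates the dominance of single-locality species without
#'   erasing genuine small-range signal; `c = 0` recovers classic
#'   inverse-range weighting.
#' @return List of class `rarity_params`.
#' @export
rarity_params <- function(c_km2 = 60000) {
  if (c_km2 < 0) stop("c_km2 must be >= 0")
  structure(list(c_km2 = c_km2,
                 equivalent_radius_km = sqrt(c_km2 / pi)),
            class = "rarity_params")
}

#' Stack range estimates into a dampened-rarity raster
#'
#' Per-cell rarity `r_i = sum_j w_ij / (a_j + c)`, where `a_j` is the
#' species' range area (for modeled species the suitability-weighted
#' area, consistent with the richness weighting). Each species'
#' contribution is strictly decreasing in its range area.
#'
#' @param ranges List of [range_estimate()] objects.
#' @param grid A [grid_spec()].
#' @param params A [rarity_params()].
#' @return A [div_raster()] with metric `"rarity"`.
#' @export
stack_rarity <- function(ranges, grid, params = rarity_params()) {
  stopifnot(inherits(params, "rarity_params"))
  v <- matrix(0, grid$n_rows, grid$n_cols)
  for (r in ranges) {
    stopifnot(inherits(r, "range_estimate"))
    if (is.null(r$area_km2) || !is.finite(r$area_km2))
      stop("range estimate lacks area_km2: ", r$species_id)
    v[r$cells] <- v[r$cells] + r$w / (r$area_km2 + params$c_km2)
  }
  v[!grid$land_mask] <- NA
  div_raster(grid, v, "rarity")
}

#' Detect diversity centers (top fraction of area)
#'
#' Ranks unmasked cells by value (descending, ties broken by cell
#' index) and accumulates spherical cell areas until the target fraction
#' of total unmasked area is reached; the accumulating cell that crosses
#' the threshold is included, so the realized fraction exceeds the
#' target by less than one cell's share. Cells in the grid's exclusion
#' mask (the Antarctica analogue) never enter the ranking. The mask is
#' scale-invariant: multiplying the raster by any positive constant
#' yields the identical center set.
#'
#' @param raster A [div_raster()].
#' @param fraction Target area fraction (default 0.10).
#' @return Object of class `center_mask`: `grid`, `member` (logical
#'   matrix), `fraction`, `realized_area_fraction`.
#' @export
detect_centers <- function(raster, fraction = 0.10) {
  stopifnot(inherits(raster, "div_raster"), fraction > 0, fraction < 1)
  g <- raster$grid
  eligible <- which(!is.na(raster$values) & !g$exclusion_mask)
  if (!length(eligible)) stop("raster has no eligible cells")
  areas <- spherical_cell_areas(g)
  ord <- eligible[order(-raster$values[eligible], eligible)]
  cum <- cumsum(areas[ord])
  total <- cum[length(cum)]
  n_in <- which(cum >= fraction * total)[1]
  member <- matrix(FALSE, g$n_rows, g$n_cols)
  member[ord[seq_len(n_in)]] <- TRUE
  structure(list(grid = g, member = member, fraction = fraction,
                 realized_area_fraction = cum[n_in] / total),
            class = "center_mask")
}

#' @export
print.center_mask <- function(x, ...) {
  cat(sprintf("<center_mask> %d cells, target %.0f%%, realized %.2f%% of area\n",
              sum(x$member), 100 * x$fraction,
              100 * x$realized_area_fraction))
  invisible(x)
}

center_area_km2 <- function(mask) {
  sum(spherical_cell_areas(mask$grid)[mask$member])
}
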