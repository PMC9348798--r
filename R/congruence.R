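#' Spearman correlation between two diversity rasters
#'
#' Rank correlation over the jointly non-NA cells, with zeros included,
#' exclusion-mask cells removed, and average ranks for ties — the
#' standard cell-level congruence statistic between taxa.
#'
#' @param a,b [div_raster()] objects on the same grid.
#' @return Spearman's rho.
#' @export
spearman_between <- function(a, b) {
  stopifnot(inherits(a, "div_raster"), inherits(b, "div_raster"))
  if (!same_grid(a$grid, b$grid)) stop("rasters are on different grids")
  ok <- !is.na(a$values) & !is.na(b$values) & !a$grid$exclusion_mask
  if (sum(ok) < 3) stop("fewer than 3 jointly non-NA cells")
  cor(a$values[ok], b$values[ok], method = "spearman")
}

#' Pairwise congruence table for a set of taxa
#'
#' @param rasters Named list of [div_raster()] objects on one grid.
#' @param fraction Center area fraction (default 0.10).
#' @return List of class `congruence_table`: `taxa`, `rho_matrix`
#'   (pairwise Spearman), `overlap_matrix` (pairwise center overlap),
#'   `resolution_arcmin`.
#' @export
congruence_table <- function(rasters, fraction = 0.10) {
  stopifnot(is.list(rasters), length(rasters) >= 2, !is.null(names(rasters)))
  k <- length(rasters)
  rho <- diag(1, k); ov <- diag(1, k)
  centers <- lapply(rasters, detect_centers, fraction = fraction)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      rho[i, j] <- rho[j, i] <- spearman_between(rasters[[i]], rasters[[j]])
      o <- overlap_fraction(centers[[i]], centers[[j]])
      ov[i, j] <- ov[j, i] <- o
    }
  }
  dimnames(rho) <- dimnames(ov) <- list(names(rasters), names(rasters))
  structure(list(taxa = names(rasters), rho_matrix = rho,
                 overlap_matrix = ov,
                 resolution_arcmin = rasters[[1]]$grid$resolution_arcmin),
            class = "congruence_table")
}

#' Overlap fraction between two diversity-center masks
#'
#' Spherical area of the intersection divided by the area of the first
#' mask. When both masks realize the same area fraction (as the
#' pipeline's equal-fraction centers do) the statistic is symmetric.
#'
#' @param a,b [detect_centers()] masks on the same grid.
#' @return Fraction in [0, 1].
#' @export
overlap_fraction <- function(a, b) {
  stopifnot(inherits(a, "center_mask"), inherits(b, "center_mask"))
  if (!same_grid(a$grid, b$grid)) stop("masks are on different grids")
  areas <- spherical_cell_areas(a$grid)
  denom <- sum(areas[a$member])
  if (denom <= 0) stop("first mask is empty")
  sum(areas[a$member & b$member]) / denom
}

#' Compare modeled richness to community-level point observations
#'
#' Community richness observations (which may include morphospecies)
#' should correlate with, and be bounded above by, the modeled regional
#' richness. For each coarsening factor the model raster is aggregated
#' by block maximum, the highest observed richness per coarse cell is
#' kept (never summing across studies), and an ordinary least-squares
#' fit of observed on modeled gives the per-resolution R^2 together with
#' the count of upper-bound violations (cells where the observation
#' exceeds the model).
#'
#' @param model_richness A [div_raster()] of modeled richness.
#' @param community_obs Data frame with columns `lon`, `lat`, `study`,
#'   `richness`.
#' @param factors Integer coarsening factors (1 = native resolution).
#' @return Data frame with columns `factor`, `resolution_arcmin`,
#'   `n_cells`, `r_squared`, `n_violations`.
#' @export
upper_bound_comparison <- function(model_richness, community_obs,
                                   factors = c(1, 2, 5)) {
  stopifnot(inherits(model_richness, "div_raster"),
            all(c("lon", "lat", "study", "richness") %in% names(community_obs)))
  out <- lapply(factors, function(f) {
    r <- if (f == 1) model_richness else coarsen_max(model_richness, f)
    rc <- cell_at(r$grid, community_obs$lon, community_obs$lat)
    idx <- cell_index(r$grid, rc$row, rc$col)
    ok <- !is.na(idx)
    per_study <- aggregate(richness ~ cell + study,
                           data = data.frame(cell = idx[ok], study = community_obs$study[ok],
                                             richness = community_obs$richness[ok]),
                           FUN = max)
    best <- aggregate(richness ~ cell, data = per_study, FUN = max)
    modeled <- r$values[best$cell]
    keep <- !is.na(modeled)
    if (sum(keep) < 3)
      return(data.frame(factor = f,
                        resolution_arcmin = r$grid$resolution_arcmin,
                        n_cells = sum(keep), r_squared = NA_real_,
                        n_violations = NA_integer_))
    fit <- lm(best$richness[keep] ~ modeled[keep])
    data.frame(factor = f, resolution_arcmin = r$grid$resolution_arcmin,
               n_cells = sum(keep),
               r_squared = summary(fit)$r.squared,
               n_violations = sum(best$richness[keep] > modeled[keep] + 1e-9))
  })
  do.call(rbind, out)
}

#' Protected-area coverage of diversity centers
#'
#' Dissolves the protected-area features to union semantics and reports
#' the fraction of the centers' spherical area whose cell centers fall
#' inside at least one protected polygon (overlapping reserves are never
#' double-counted).
#'
#' @param centers A [detect_centers()] mask.
#' @param protected List of [geo_polygon()] features (dissolved
#'   internally if needed).
#' @return List of class `coverage_result`: `metric`,
#'   `protected_fraction`, `center_area_km2`.
#' @export
protected_coverage <- function(centers, protected) {
  stopifnot(inherits(centers, "center_mask"))
  polys <- dissolve_polygons(protected)
  g <- centers$grid
  idx <- which(centers$member)
  if (!length(idx)) stop("empty center mask")
  cc <- cell_centers(g)
  row <- (idx - 1L) %% g$n_rows + 1L
  col <- (idx - 1L) %/% g$n_rows + 1L
  inside <- point_in_any(polys, cc$lon[col], cc$lat[row])
  areas <- spherical_cell_areas(g)
  structure(list(metric = "center_coverage",
                 protected_fraction = sum(areas[idx][inside]) / sum(areas[idx]),
                 center_area_km2 = sum(areas[idx])),
            class = "coverage_result")
}
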