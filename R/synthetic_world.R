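#' Seeded smooth random field
#'
#' Low-frequency random surface used for synthetic environments, land
#' masks and sampling-bias fields: a sum of `n_components` random cosine
#' plane waves (frequencies of 1-7 cycles across the domain) plus a
#' latitudinal gradient term with a random coefficient. Values are
#' standardized to mean 0, sd 1 over the whole grid.
#'
#' @param grid A [grid_spec()].
#' @param seed Integer seed; the field is bit-reproducible given
#'   (grid, seed, n_components).
#' @param n_components Number of cosine components (default 12).
#' @param lat_gradient_sd Spread of the random latitude-gradient
#'   coefficient.
#' @return Numeric matrix `n_rows x n_cols`.
#' @export
smooth_field <- function(grid, seed, n_components = 12, lat_gradient_sd = 0.3) {
  set.seed(seed)
  cc <- cell_centers(grid)
  u <- (cc$lon - grid$lon_min) / (grid$lon_max - grid$lon_min)
  v <- (cc$lat - grid$lat_min) / (grid$lat_max - grid$lat_min)
  U <- matrix(u, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
  V <- matrix(v, nrow = grid$n_rows, ncol = grid$n_cols)
  f <- matrix(0, grid$n_rows, grid$n_cols)
  for (k in seq_len(n_components)) {
    amp <- rnorm(1)
    fu <- runif(1, 1, 7) * sample(c(-1, 1), 1)
    fv <- runif(1, 1, 7) * sample(c(-1, 1), 1)
    ph <- runif(1, 0, 2 * pi)
    f <- f + amp * cos(2 * pi * (fu * U + fv * V) + ph)
  }
  g <- rnorm(1, 0, lat_gradient_sd)
  latdeg <- matrix(cc$lat, nrow = grid$n_rows, ncol = grid$n_cols)
  f <- f + g * n_components / 4 * cos(latdeg * pi / 180)
  (f - mean(f)) / sd(f)
}

#' Generate a synthetic environmental stack
#'
#' Stands in for a set of bioclimatic layers: each layer is an
#' independent seeded [smooth_field()], standardized to mean 0 and sd 1
#' over land cells. Layers are named `env_1 ... env_k`.
#'
#' @param grid A [grid_spec()] with at least one land cell.
#' @param n_layers Number of layers (>= 1).
#' @param seed Integer seed.
#' @return Object of class `env_stack`: list with `grid`, `layers`
#'   (named list of matrices, NA on water) and `seed`.
#' @export
generate_environment <- function(grid, n_layers, seed) {
  stopifnot(inherits(grid, "grid_spec"))
  if (n_layers < 1) stop("n_layers must be >= 1")
  if (!any(grid$land_mask)) stop("degenerate grid: no land cells")
  layers <- list()
  for (k in seq_len(n_layers)) {
    f <- smooth_field(grid, seed = seed + 1000L * k, n_components = 12)
    f[!grid$land_mask] <- NA
    mu <- mean(f, na.rm = TRUE); s <- sd(f, na.rm = TRUE)
    layers[[sprintf("env_%d", k)]] <- (f - mu) / s
  }
  structure(list(grid = grid, layers = layers, seed = seed),
            class = "env_stack")
}

#' Generate a synthetic species pool with log-normal range sizes
#'
#' Each species receives a climatic niche center (the environment of a
#' random land cell, slightly perturbed) and a target range area drawn
#' from a log-normal distribution. Its true occupancy is grown as a
#' contiguous patch from the seed cell, adding the neighboring land cell
#' with the smallest environmental distance to the niche center until
#' the accumulated spherical area reaches the target (so the realized
#' area exceeds the target by at most one cell). Species whose target
#' exceeds the reachable land are truncated and flagged.
#'
#' @param env An `env_stack` from [generate_environment()].
#' @param n_species Number of species (>= 1).
#' @param log_range_mu,log_range_sigma Parameters of the log-normal
#'   target range-area distribution (km^2 scale; defaults give a median
#'   range of 600,000 km^2 with heavy right skew, leaving most of the
#'   land occupied by at least one species as global compilations of a
#'   ubiquitous taxon are).
#' @param seed Integer seed.
#' @return List of `true_species` objects: `species_id`, `niche_center`,
#'   `niche_breadth` (max environmental distance realized), `cells`
#'   (occupied cell indices), `true_area_km2`, `truncated`.
#' @export
generate_species_pool <- function(env, n_species,
                                  log_range_mu = log(6e5),
                                  log_range_sigma = 1.3, seed = 1) {
  stopifnot(inherits(env, "env_stack"), n_species >= 1)
  set.seed(seed)
  grid <- env$grid
  areas <- spherical_cell_areas(grid)
  land_idx <- which(grid$land_mask)
  emat <- sapply(env$layers, function(m) m[land_idx])  # n_land x k
  if (is.null(dim(emat))) emat <- matrix(emat, ncol = 1)
  pos <- match(seq_len(grid$n_rows * grid$n_cols), land_idx)  # cell -> land row
  wrap <- isTRUE(all.equal(grid$lon_max - grid$lon_min, 360))
  nr <- grid$n_rows; nc <- grid$n_cols
  neighbors <- function(ci) {
    r <- (ci - 1L) %% nr + 1L; cl <- (ci - 1L) %/% nr + 1L
    out <- integer(0)
    if (r > 1) out <- c(out, ci - 1L)
    if (r < nr) out <- c(out, ci + 1L)
    left <- if (cl > 1) ci - nr else if (wrap) ci + nr * (nc - 1L) else NA
    right <- if (cl < nc) ci + nr else if (wrap) ci - nr * (nc - 1L) else NA
    c(out, left[!is.na(left)], right[!is.na(right)])
  }
  targets <- rlnorm(n_species, log_range_mu, log_range_sigma)
  seeds <- sample(land_idx, n_species, replace = TRUE)
  pool <- vector("list", n_species)
  for (j in seq_len(n_species)) {
    center <- emat[pos[seeds[j]], ] + rnorm(ncol(emat), 0, 0.1)
    # environmental distance of every land cell to the niche center
    dist2 <- rowSums((emat - matrix(center, nrow(emat), ncol(emat), byrow = TRUE))^2)
    occupied <- seeds[j]
    in_set <- rep(FALSE, nr * nc); in_set[seeds[j]] <- TRUE
    cum_area <- areas[seeds[j]]
    frontier <- setdiff(neighbors(seeds[j]), occupied)
    frontier <- frontier[grid$land_mask[frontier]]
    while (cum_area < targets[j] && length(frontier)) {
      fd <- dist2[pos[frontier]]
      b <- frontier[which.min(fd)]
      in_set[b] <- TRUE
      occupied <- c(occupied, b)
      cum_area <- cum_area + areas[b]
      frontier <- frontier[frontier != b]
      nb <- neighbors(b)
      nb <- nb[grid$land_mask[nb] & !in_set[nb] & !(nb %in% frontier)]
      frontier <- c(frontier, nb)
    }
    pool[[j]] <- structure(list(
      species_id = sprintf("sp_%04d", j),
      niche_center = center,
      niche_breadth = sqrt(max(dist2[pos[occupied]])),
      cells = sort(occupied),
      target_area_km2 = targets[j],
      true_area_km2 = cum_area,
      truncated = cum_area < targets[j]), class = "true_species")
  }
  pool
}

#' True richness of a synthetic species pool
#'
#' @param pool List from [generate_species_pool()].
#' @param grid The pool's [grid_spec()].
#' @return A [div_raster()] of true per-cell species counts (NA water).
#' @export
true_richness <- function(pool, grid) {
  v <- matrix(0, grid$n_rows, grid$n_cols)
  for (sp in pool) v[sp$cells] <- v[sp$cells] + 1
  v[!grid$land_mask] <- NA
  div_raster(grid, v, "richness")
}

#' True dampened rarity of a synthetic species pool
#'
#' Per-cell sum of `1 / (a_j + c)` over species truly present, using the
#' true range areas.
#'
#' @inheritParams true_richness
#' @param c_km2 Damping constant added to each range area (km^2).
#' @return A [div_raster()] with metric `"rarity"`.
#' @export
true_rarity <- function(pool, grid, c_km2 = 60000) {
  v <- matrix(0, grid$n_rows, grid$n_cols)
  for (sp in pool) v[sp$cells] <- v[sp$cells] + 1 / (sp$true_area_km2 + c_km2)
  v[!grid$land_mask] <- NA
  div_raster(grid, v, "rarity")
}

#' Generate a spatial sampling-bias field
#'
#' A smooth collection-effort surface in [0, 1]: a seeded smooth field
#' pushed through a logistic contrast transform and rescaled so its
#' maximum over land is exactly 1; zero outside land. The bias is purely
#' spatial (independent of species identity), matching the assumption of
#' the downstream bias-corrected background sampling and the Random
#' Forest counterfactual.
#'
#' @param grid A [grid_spec()].
#' @param seed Integer seed.
#' @param contrast Logistic steepness; larger values give stronger
#'   well-sampled / unsampled contrast (default 2).
#' @return Object of class `bias_field`: list with `grid` and `density`
#'   matrix.
#' @export
make_bias_field <- function(grid, seed, contrast = 2) {
  f <- smooth_field(grid, seed = seed, n_components = 8)
  d <- 1 / (1 + exp(-contrast * f))
  d[!grid$land_mask] <- 0
  d <- d / max(d)
  structure(list(grid = grid, density = d), class = "bias_field")
}

#' Build a synthetic gazetteer
#'
#' Partitions land into countries and first-level admin units (spherical
#' Voronoi cells of random seed locations) and registers one named
#' locality per land cell with exact coordinates inside that cell. Admin
#' and country centroids (spherical means of member cells) are recorded
#' to support centroid-flagging. Stands in for the locality-validation
#' databases and geocoder returns a real pipeline would query.
#'
#' @param grid A [grid_spec()].
#' @param seed Integer seed.
#' @param n_countries Number of synthetic countries.
#' @param n_admin_per Admin units per country.
#' @return Object of class `gazetteer`: `entries` data frame (locality,
#'   lon, lat, admin1, country, precision_radius_km), `centroids` data
#'   frame, `country_raster` and `admin_raster` matrices, `grid`.
#' @export
make_gazetteer <- function(grid, seed, n_countries = 12, n_admin_per = 3) {
  set.seed(seed)
  land_idx <- which(grid$land_mask)
  cc <- cell_centers(grid)
  row <- (land_idx - 1L) %% grid$n_rows + 1L
  col <- (land_idx - 1L) %/% grid$n_rows + 1L
  lon <- cc$lon[col]; lat <- cc$lat[row]
  unitv <- cbind(cos(lat * pi / 180) * cos(lon * pi / 180),
                 cos(lat * pi / 180) * sin(lon * pi / 180),
                 sin(lat * pi / 180))
  vor <- function(idx_subset, k) {
    sel <- sample(seq_along(idx_subset), min(k, length(idx_subset)))
    seeds_v <- unitv[idx_subset[sel], , drop = FALSE]
    sim <- unitv[idx_subset, , drop = FALSE] %*% t(seeds_v)
    max.col(sim, ties.method = "first")
  }
  country_id <- vor(seq_along(land_idx), n_countries)
  country_names <- sprintf("Country_%02d", seq_len(max(country_id)))
  admin_names <- character(length(land_idx))
  for (k in seq_len(max(country_id))) {
    members <- which(country_id == k)
    aid <- vor(members, n_admin_per)
    admin_names[members] <- sprintf("%s:adm%d", country_names[k], aid)
  }
  country_raster <- matrix(NA_character_, grid$n_rows, grid$n_cols)
  admin_raster <- matrix(NA_character_, grid$n_rows, grid$n_cols)
  country_raster[land_idx] <- country_names[country_id]
  admin_raster[land_idx] <- admin_names
  sph_centroid <- function(sel) {
    v <- colMeans(unitv[sel, , drop = FALSE])
    v <- v / sqrt(sum(v^2))
    # snap to the member cell nearest the spherical mean, so the unit's
    # centroid always lies on its own territory (label-point convention)
    best <- sel[which.max(unitv[sel, , drop = FALSE] %*% v)]
    c(lon[best], lat[best])
  }
  units <- c(setNames(lapply(seq_len(max(country_id)),
                             function(k) which(country_id == k)),
                      country_names),
             lapply(split(seq_along(land_idx), admin_names), identity))
  cent <- t(vapply(units, sph_centroid, c(0, 0)))
  centroids <- data.frame(unit = names(units),
                          level = c(rep("country", max(country_id)),
                                    rep("admin1", length(units) - max(country_id))),
                          lon = cent[, 1], lat = cent[, 2],
                          stringsAsFactors = FALSE)
  step <- grid_step(grid)
  entries <- data.frame(
    locality = sprintf("loc_%06d", land_idx),
    lon = lon + runif(length(land_idx), -0.45, 0.45) * step,
    lat = lat + runif(length(land_idx), -0.45, 0.45) * step,
    admin1 = admin_names,
    country = country_names[country_id],
    precision_radius_km = runif(length(land_idx), 0, 20),
    cell = land_idx,
    stringsAsFactors = FALSE)
  structure(list(entries = entries, centroids = centroids,
                 country_raster = country_raster, admin_raster = admin_raster,
                 grid = grid),
            class = "gazetteer")
}

#' Look up the country of coordinates
#'
#' @param gazetteer A [make_gazetteer()] object.
#' @param lon,lat Coordinate vectors.
#' @return Character vector of country names (NA on water / outside).
#' @export
lookup_country <- function(gazetteer, lon, lat) {
  rc <- cell_at(gazetteer$grid, lon, lat)
  out <- rep(NA_character_, length(lon))
  ok <- !is.na(rc$row)
  out[ok] <- gazetteer$country_raster[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Record-noise configuration for the synthetic collector
#'
#' Fractions of simulated records that carry each class of metadata
#' defect. Defaults emulate a literature-plus-museum compilation: about a
#' third of records lack coordinates and must be geocoded from their
#' locality string, geocode precision radii follow a mixture with a 10%
#' tail above the 100-km usability cutoff, a small fraction of records
#' carry a wrong country label or sit exactly on an admin centroid, and a
#' fifth are verbatim duplicates of an existing locality.
#'
#' @param p_missing_coords Fraction lacking original coordinates.
#' @param p_wrong_country Fraction with a mislabeled country.
#' @param p_gt100_precision Fraction whose geocode precision radius is
#'   drawn above 100 km (100-500 km); the remainder is 80% U(0, 20) and
#'   20% U(20, 100).
#' @param p_duplicate Fraction of extra rows appended as exact duplicates.
#' @param p_centroid Fraction georeferenced to their country centroid
#'   with a country-only locality string.
#' @return List of class `noise_config`.
#' @export
noise_config <- function(p_missing_coords = 0.35, p_wrong_country = 0.02,
                         p_gt100_precision = 0.10, p_duplicate = 0.20,
                         p_centroid = 0.02) {
  p <- list(p_missing_coords = p_missing_coords,
            p_wrong_country = p_wrong_country,
            p_gt100_precision = p_gt100_precision,
            p_duplicate = p_duplicate,
            p_centroid = p_centroid)
  stopifnot(all(unlist(p) >= 0), all(unlist(p) <= 1))
  structure(p, class = "noise_config")
}

empty_record_table <- function() {
  data.frame(record_id = integer(0), species_id = character(0),
             locality_text = character(0), country_label = character(0),
             admin1_label = character(0), orig_lon = numeric(0),
             orig_lat = numeric(0), geo_lon = numeric(0), geo_lat = numeric(0),
             precision_radius_km = numeric(0),
             true_lon = numeric(0), true_lat = numeric(0),
             truth_missing = logical(0), truth_wrong_country = logical(0),
             truth_centroid = logical(0), truth_duplicate = logical(0),
             stringsAsFactors = FALSE)
}

#' Simulate a biased, noisy collection process
#'
#' Draws occurrence records for each species: the number of records in
#' each truly occupied cell is Poisson with mean `effort * density`, so
#' sampling intensity is purely spatial and conditionally independent of
#' species identity given location. Each record is anchored to the
#' cell's gazetteer locality; the configured noise fractions then remove
#' original coordinates, mislabel countries, inflate geocode precision
#' radii, move records onto country centroids, or append verbatim
#' duplicates. Ground-truth columns (`truth_*`, `true_lon/lat`) make QC
#' precision/recall exactly scorable.
#'
#' @param pool Species list from [generate_species_pool()].
#' @param bias A [make_bias_field()] object.
#' @param effort Expected records per occupied cell at density 1.
#' @param noise A [noise_config()].
#' @param gazetteer A [make_gazetteer()] object on the same grid.
#' @param seed Integer seed.
#' @return Data frame of occurrence records (one row per record).
#' @export
simulate_collection <- function(pool, bias, effort, noise, gazetteer, seed) {
  stopifnot(inherits(bias, "bias_field"), inherits(noise, "noise_config"),
            inherits(gazetteer, "gazetteer"))
  set.seed(seed)
  if (!length(pool)) return(empty_record_table())
  ent <- gazetteer$entries
  ent_of_cell <- match(seq_len(nrow(gazetteer$country_raster) *
                                 ncol(gazetteer$country_raster)), ent$cell)
  recs <- list()
  for (sp in pool) {
    lam <- effort * bias$density[sp$cells]
    n <- rpois(length(lam), lam)
    cells <- rep(sp$cells, n)
    if (!length(cells)) next
    recs[[sp$species_id]] <- data.frame(species_id = sp$species_id,
                                        cell = cells, stringsAsFactors = FALSE)
  }
  if (!length(recs)) return(empty_record_table())
  df <- do.call(rbind, recs)
  e <- ent[ent_of_cell[df$cell], ]
  n <- nrow(df)
  countries <- unique(ent$country)
  cent <- gazetteer$centroids
  ccent <- cent[cent$level == "country", ]
  # precision-radius mixture
  u <- runif(n)
  radius <- ifelse(u < noise$p_gt100_precision, runif(n, 100, 500),
                   ifelse(runif(n) < 0.8, runif(n, 0, 20), runif(n, 20, 100)))
  # noise classes are exclusive per record so ground-truth labels score
  # each QC flag unambiguously
  centr <- runif(n) < noise$p_centroid
  miss <- !centr & runif(n) < noise$p_missing_coords
  wrongc <- !centr & !miss & runif(n) < noise$p_wrong_country
  out <- data.frame(
    record_id = seq_len(n),
    species_id = df$species_id,
    locality_text = e$locality,
    country_label = e$country,
    admin1_label = e$admin1,
    orig_lon = e$lon, orig_lat = e$lat,
    geo_lon = e$lon, geo_lat = e$lat,
    precision_radius_km = radius,
    true_lon = e$lon, true_lat = e$lat,
    truth_missing = miss, truth_wrong_country = wrongc,
    truth_centroid = centr, truth_duplicate = FALSE,
    stringsAsFactors = FALSE)
  out$orig_lon[miss] <- NA; out$orig_lat[miss] <- NA
  if (any(wrongc)) {
    shift <- sample(length(countries) - 1, sum(wrongc), replace = TRUE)
    cur <- match(out$country_label[wrongc], countries)
    out$country_label[wrongc] <-
      countries[(cur - 1 + shift) %% length(countries) + 1]
  }
  if (any(centr)) {
    truec <- lookup_country(gazetteer, out$true_lon[centr], out$true_lat[centr])
    m <- match(truec, ccent$unit)
    out$locality_text[centr] <- truec
    out$orig_lon[centr] <- ccent$lon[m]; out$orig_lat[centr] <- ccent$lat[m]
    out$geo_lon[centr] <- ccent$lon[m]; out$geo_lat[centr] <- ccent$lat[m]
    out$precision_radius_km[centr] <- pmax(out$precision_radius_km[centr], 150)
  }
  n_dup <- round(noise$p_duplicate * n)
  if (n_dup > 0) {
    dup <- out[sample(n, n_dup, replace = TRUE), ]
    dup$truth_duplicate <- TRUE
    out <- rbind(out, dup)
    out$record_id <- seq_len(nrow(out))
  }
  rownames(out) <- NULL
  out
}

#' Generate a companion-taxon diversity raster at a target rank
#' correlation
#'
#' Emulates an independently mapped comparison taxon (e.g. a vertebrate
#' group) whose grid-cell diversity has a controlled Spearman correlation
#' with a reference raster. Normal scores of the reference ranks are
#' mixed with normal scores of an independent smooth field using the
#' Gaussian-copula relation `rho_pearson = 2 sin(pi rho_s / 6)`, so the
#' measured Spearman correlation over land converges to `rho_target`.
#'
#' @param reference A [div_raster()] with >= 100 unmasked cells.
#' @param rho_target Target Spearman correlation in [-1, 1];
#'   `rho_target = 1` returns a copy of the reference.
#' @param seed Integer seed.
#' @return A [div_raster()] on the same grid.
#' @export
generate_companion_taxa <- function(reference, rho_target, seed) {
  stopifnot(inherits(reference, "div_raster"))
  if (abs(rho_target) > 1) stop("rho_target must lie in [-1, 1]")
  idx <- which(!is.na(reference$values))
  if (length(idx) < 100) stop("reference needs >= 100 unmasked cells")
  if (rho_target == 1) {
    out <- reference; out$metric <- "companion"
    return(out)
  }
  f <- smooth_field(reference$grid, seed = seed, n_components = 12)
  nsc <- function(x) qnorm(rank(x, ties.method = "average") / (length(x) + 1))
  x <- nsc(reference$values[idx])
  y <- nsc(f[idx])
  rp <- 2 * sin(pi * rho_target / 6)
  z <- rp * x + sqrt(1 - rp^2) * y
  v <- matrix(NA_real_, reference$grid$n_rows, reference$grid$n_cols)
  v[idx] <- z - min(z)  # diversity surfaces are non-negative
  div_raster(reference$grid, v, "companion")
}

#' Generate synthetic protected-area polygons
#'
#' Emits random rectangular reserves over land until their union covers
#' `target_fraction` of the land area (within about 2%). Features may
#' overlap, so downstream coverage code must dissolve them.
#'
#' @param grid A [grid_spec()].
#' @param target_fraction Target covered fraction of land in (0, 1).
#' @param seed Integer seed.
#' @return List of [geo_polygon()] rectangles with attribute
#'   `covered_fraction` (realized union coverage of land).
#' @export
generate_protected_areas <- function(grid, target_fraction, seed) {
  stopifnot(target_fraction > 0, target_fraction < 1)
  set.seed(seed)
  areas <- spherical_cell_areas(grid)
  land_idx <- which(grid$land_mask)
  total <- sum(areas[land_idx])
  cc <- cell_centers(grid)
  covered <- matrix(FALSE, grid$n_rows, grid$n_cols)
  polys <- list()
  frac <- 0
  while (frac < target_fraction && length(polys) < 5000) {
    ci <- sample(land_idx, 1)
    r <- (ci - 1L) %% grid$n_rows + 1L; cl <- (ci - 1L) %/% grid$n_rows + 1L
    hw <- runif(1, 1, 3); hh <- runif(1, 1, 3)
    x0 <- max(grid$lon_min, cc$lon[cl] - hw)
    x1 <- min(grid$lon_max, cc$lon[cl] + hw)
    y0 <- max(grid$lat_min, cc$lat[r] - hh)
    y1 <- min(grid$lat_max, cc$lat[r] + hh)
    polys[[length(polys) + 1]] <-
      geo_polygon(list(cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))))
    cols <- which(cc$lon > x0 & cc$lon < x1)
    rows <- which(cc$lat > y0 & cc$lat < y1)
    covered[rows, cols] <- TRUE
    frac <- sum(areas[covered & grid$land_mask]) / total
  }
  attr(polys, "covered_fraction") <- frac
  polys
}

#' Assemble a complete synthetic world
#'
#' Convenience constructor wiring together the default study conditions
#' used throughout the package's tests and examples: a 1-degree grid over
#' a +-60 degree latitude band with smooth-field continents and a polar
#' exclusion band, a 3-layer environment, a log-normal species pool,
#' spatially biased collection effort, record noise, a gazetteer, a
#' companion taxon correlated with true richness, and protected areas.
#'
#' @param seed Master seed; every component derives its own stream from
#'   it.
#' @param resolution_arcmin Grid resolution (default 60 = 1 degree).
#' @param n_species Species-pool size (default 150).
#' @param n_layers Environmental layers (default 3).
#' @param effort Expected records per occupied cell at density 1.
#' @param noise A [noise_config()].
#' @param companion_rho Spearman correlation between the companion taxon
#'   and true richness (default 0.75).
#' @param protect_fraction Protected-area target coverage (default 0.15).
#' @param lat_band Half-width of the latitude band in degrees.
#' @return List with components `grid`, `env`, `pool`, `bias`,
#'   `gazetteer`, `records`, `companion`, `protected`, `seed`.
#' @export
synthetic_world <- function(seed = 1, resolution_arcmin = 60, n_species = 150,
                            n_layers = 3, effort = 1.5,
                            noise = noise_config(), companion_rho = 0.75,
                            protect_fraction = 0.15, lat_band = 60) {
  base <- grid_spec(resolution_arcmin, lat_min = -lat_band, lat_max = lat_band)
  land <- smooth_field(base, seed = seed + 11L, n_components = 10) >
    qnorm(1 - 0.35)  # ~35% land
  excl <- matrix(FALSE, base$n_rows, base$n_cols)
  lat <- cell_centers(base)$lat
  excl[lat < -(lat_band - 10), ] <- TRUE  # polar exclusion band
  grid <- grid_spec(resolution_arcmin, lat_min = -lat_band, lat_max = lat_band,
                    land_mask = land, exclusion_mask = excl)
  env <- generate_environment(grid, n_layers, seed = seed + 23L)
  pool <- generate_species_pool(env, n_species, seed = seed + 37L)
  bias <- make_bias_field(grid, seed = seed + 53L)
  gaz <- make_gazetteer(grid, seed = seed + 71L)
  records <- simulate_collection(pool, bias, effort, noise, gaz,
                                 seed = seed + 89L)
  companion <- generate_companion_taxa(true_richness(pool, grid),
                                       companion_rho, seed = seed + 101L)
  protected <- generate_protected_areas(grid, protect_fraction,
                                        seed = seed + 127L)
  list(grid = grid, env = env, pool = pool, bias = bias, gazetteer = gaz,
       records = records, companion = companion, protected = protected,
       seed = seed)
}
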