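#' Default pipeline configuration
#'
#' Assembles the full parameter set of the analysis chain. Every stage
#' parameter defaults to the value used for the headline analysis:
#' 30-km buffers, alpha 15, 10-km thinning, 100-km precision cutoff,
#' 10,000 background points, feature classes L/LQ/H/LQH with
#' multipliers 1-5, rarity constant 60,000 km^2, 10% centers, 0.7
#' collinearity threshold, mtry 1-10 on a 10 x 14 checkerboard, and
#' 60-cell rarefaction windows. The `synthetic` block parameterizes the
#' generated world.
#'
#' @param seed Master seed; each stage derives its own stream.
#' @param ... Named overrides of any default (unknown names are an
#'   error in [validate_config()]).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    synthetic = list(resolution_arcmin = 60, n_species = 150, n_layers = 3,
                     effort = 1.5, companion_rho = 0.75,
                     protect_fraction = 0.15, lat_band = 60),
    qc = list(max_precision_km = 100, centroid_tol_km = 1),
    ranges = list(buffer_km = 30, alpha = 15, thin_km = 10),
    sdm = list(classes = c("L", "LQ", "H", "LQH"), multipliers = 1:5,
               n_background = 10000, hinge_knots = 8, enabled = TRUE),
    rarity = list(c_km2 = 60000),
    centers = list(fraction = 0.10),
    biasmodel = list(collinearity_threshold = 0.7, mtry_grid = 1:10,
                     n_trees = 500, block_rows = 10, block_cols = 14, k = 5),
    rarefy = list(window_cells = 60, stride = 30))
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm %in% names(cfg) && is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Type and range checks on every stage parameter; an empty return
#' means the configuration is valid.
#'
#' @param config A [pipeline_config()].
#' @return Character vector of problems (length 0 when valid).
#' @export
validate_config <- function(config) {
  p <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) p <<- c(p, msg)
  chk(is.numeric(config$seed) && length(config$seed) == 1,
      "seed must be a single number")
  s <- config$synthetic
  chk(s$resolution_arcmin > 0, "synthetic$resolution_arcmin must be > 0")
  chk(s$n_species >= 1, "synthetic$n_species must be >= 1")
  chk(s$effort > 0, "synthetic$effort must be > 0")
  chk(abs(s$companion_rho) <= 1, "synthetic$companion_rho must be in [-1, 1]")
  chk(s$protect_fraction > 0 && s$protect_fraction < 1,
      "synthetic$protect_fraction must be in (0, 1)")
  chk(config$qc$max_precision_km > 0, "qc$max_precision_km must be > 0")
  chk(config$qc$centroid_tol_km >= 0, "qc$centroid_tol_km must be >= 0")
  chk(config$ranges$buffer_km > 0, "ranges$buffer_km must be > 0")
  chk(config$ranges$alpha > 0, "ranges$alpha must be > 0")
  chk(config$ranges$thin_km > 0, "ranges$thin_km must be > 0")
  chk(all(config$sdm$classes %in% c("L", "LQ", "H", "LQH")),
      "sdm$classes must be a subset of L, LQ, H, LQH")
  chk(all(config$sdm$multipliers >= 1), "sdm$multipliers must be >= 1")
  chk(config$sdm$n_background >= 100, "sdm$n_background must be >= 100")
  chk(config$rarity$c_km2 >= 0, "rarity$c_km2 must be >= 0")
  chk(config$centers$fraction > 0 && config$centers$fraction < 1,
      "centers$fraction must be in (0, 1)")
  chk(config$biasmodel$collinearity_threshold > 0 &&
        config$biasmodel$collinearity_threshold <= 1,
      "biasmodel$collinearity_threshold must be in (0, 1]")
  chk(all(config$biasmodel$mtry_grid >= 1), "biasmodel$mtry_grid must be >= 1")
  chk(config$rarefy$window_cells >= 2, "rarefy$window_cells must be >= 2")
  p
}

stage_seed <- function(master, stage) {
  offsets <- c(world = 0L, qc = 101L, ranges = 211L, sdm = 307L,
               stack = 401L, centers = 503L, congruence = 601L,
               biasmodel = 701L, treasure = 809L, rarefy = 907L,
               protect = 1009L)
  as.integer((as.integer(master) + 13L * offsets[[stage]]) %% 2147483647L)
}

#' Run the full pipeline on a synthetic world
#'
#' Executes the complete chain: world generation, occurrence QC, range
#' estimation (with or without the suitability-model branch), richness
#' and rarity stacking, center detection, companion-taxon congruence,
#' the Random Forest sampling-bias model with its high-sampling
#' counterfactual, moving-window rarefaction, and protected-area
#' coverage. All stochastic stages draw seeds derived deterministically
#' from the master seed, so a rerun with the same configuration
#' reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param skip_sdm Use univalue polygons for every species (the
#'   sensitivity variant that drops the suitability-model branch).
#' @param quiet Suppress progress messages.
#' @return List of class `pipeline_run`: `world`, `qc`, `ranges`,
#'   `richness`, `rarity`, `centers` (list with both metrics),
#'   `congruence`, `biasmodel` (fits and counterfactuals per metric),
#'   `rarefaction`, `protection`, and `manifest` (per-stage parameters,
#'   seeds, durations, output hashes).
#' @export
run_pipeline <- function(config = pipeline_config(), skip_sdm = FALSE,
                         quiet = TRUE) {
  problems <- validate_config(config)
  if (length(problems)) stop("invalid config: ", paste(problems, collapse = "; "))
  manifest <- list()
  note <- function(stage, params, out) {
    manifest[[stage]] <<- list(params = params, seed = stage_seed(config$seed, stage),
                               duration_s = round(as.numeric(Sys.time()) - t0, 2),
                               hash = rlang::hash(out))
    if (!quiet) message(sprintf("[%s] done in %.1fs", stage,
                                manifest[[stage]]$duration_s))
  }
  # --- synthetic world
  t0 <- as.numeric(Sys.time())
  s <- config$synthetic
  world <- synthetic_world(seed = stage_seed(config$seed, "world"),
                           resolution_arcmin = s$resolution_arcmin,
                           n_species = s$n_species, n_layers = s$n_layers,
                           effort = s$effort, companion_rho = s$companion_rho,
                           protect_fraction = s$protect_fraction,
                           lat_band = s$lat_band)
  grid <- world$grid
  note("world", s, world$records)
  # --- occurrence QC
  t0 <- as.numeric(Sys.time())
  qc <- qc_pipeline(world$records, world$gazetteer,
                    max_precision_km = config$qc$max_precision_km,
                    centroid_tol_km = config$qc$centroid_tol_km)
  note("qc", config$qc, qc$report)
  # --- sampling density from all retained localities
  t0 <- as.numeric(Sys.time())
  pts <- cbind(qc$retained$resolved_lon, qc$retained$resolved_lat)
  density <- build_sampling_density(pts, grid)
  # --- ranges
  by_sp <- split(seq_len(nrow(qc$retained)), qc$retained$species_id)
  ranges <- vector("list", length(by_sp))
  names(ranges) <- names(by_sp)
  for (sp in names(by_sp)) {
    spts <- pts[by_sp[[sp]], , drop = FALSE]
    sd_args <- if (skip_sdm) list() else
      list(classes = config$sdm$classes,
           multipliers = config$sdm$multipliers,
           hinge_knots = config$sdm$hinge_knots)
    ranges[[sp]] <- tryCatch(
      estimate_range(sp, spts, grid,
                     env = if (skip_sdm || !config$sdm$enabled) NULL else world$env,
                     bias = density,
                     seed = stage_seed(config$seed, "ranges") +
                       match(sp, names(by_sp)),
                     alpha = config$ranges$alpha,
                     buffer_km = config$ranges$buffer_km,
                     thin_km = config$ranges$thin_km,
                     sdm_args = sd_args),
      error = function(e) NULL)
  }
  ranges <- Filter(Negate(is.null), ranges)
  note("ranges", config$ranges,
       vapply(ranges, function(r) r$area_km2, 0))
  # --- stacking and centers
  t0 <- as.numeric(Sys.time())
  richness <- stack_richness(ranges, grid)
  rarity <- stack_rarity(ranges, grid, rarity_params(config$rarity$c_km2))
  centers <- list(richness = detect_centers(richness, config$centers$fraction),
                  rarity = detect_centers(rarity, config$centers$fraction))
  note("stack", c(config$rarity, config$centers),
       list(richness$values, rarity$values))
  # --- congruence with the companion taxon
  t0 <- as.numeric(Sys.time())
  congr <- congruence_table(list(focal = richness,
                                 companion = world$companion),
                            fraction = config$centers$fraction)
  note("congruence", list(fraction = config$centers$fraction), congr$rho_matrix)
  # --- sampling-bias Random Forest per metric
  t0 <- as.numeric(Sys.time())
  realm <- world$gazetteer$country_raster  # realm analogue
  layers <- c(world$env$layers,
              list(companion = world$companion$values,
                   sampling_density = density$density))
  stack <- predictor_stack(grid, layers, realm = realm)
  retained <- screen_collinearity(stack, config$biasmodel$collinearity_threshold)
  folds <- checkerboard_folds(grid, config$biasmodel$block_rows,
                              config$biasmodel$block_cols, config$biasmodel$k)
  biasmodel <- list()
  for (metric in c("richness", "rarity")) {
    resp <- if (metric == "richness") richness else rarity
    fit <- tune_mtry(stack, resp, folds,
                     mtry_grid = config$biasmodel$mtry_grid,
                     n_trees = config$biasmodel$n_trees,
                     response_transform = if (metric == "rarity") "log"
                                          else "identity",
                     retained = retained,
                     seed = stage_seed(config$seed, "biasmodel"))
    cf <- counterfactual_high_sampling(fit, stack, config$centers$fraction)
    biasmodel[[metric]] <- list(fit = fit, counterfactual = cf,
                                robustness = robustness_fraction(cf))
  }
  note("biasmodel", config$biasmodel,
       lapply(biasmodel, function(b) b$robustness))
  # --- moving-window rarefaction
  t0 <- as.numeric(Sys.time())
  rc <- cell_at(grid, qc$retained$resolved_lon, qc$retained$resolved_lat)
  occ_cells <- split(cell_index(grid, rc$row, rc$col), qc$retained$species_id)
  occ_cells <- lapply(occ_cells, function(x) unique(x[!is.na(x)]))
  rarefaction <- moving_window_map(occ_cells, grid,
                                   window_cells = min(config$rarefy$window_cells,
                                                      grid$n_rows),
                                   stride = config$rarefy$stride)
  note("rarefy", config$rarefy, rarefaction$windows)
  # --- protected-area coverage of centers
  t0 <- as.numeric(Sys.time())
  protection <- lapply(centers, protected_coverage, protected = world$protected)
  note("protect", list(), lapply(protection, `[[`, "protected_fraction"))
  structure(list(world = world, qc = qc, density = density, ranges = ranges,
                 richness = richness, rarity = rarity, centers = centers,
                 congruence = congr, biasmodel = biasmodel,
                 rarefaction = rarefaction, protection = protection,
                 manifest = manifest, config = config),
            class = "pipeline_run")
}
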