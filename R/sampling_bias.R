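#' Assemble a predictor stack for the sampling-bias model
#'
#' Aligned per-cell predictor layers for the Random Forest: continuous
#' layers (climate, topography analogue, companion-taxon diversity), the
#' sampling-density layer (exempt from collinearity screening, and the
#' layer the counterfactual later sets to 1), and one categorical realm
#' layer (one-hot encoded at training time).
#'
#' @param grid A [grid_spec()].
#' @param layers Named list of numeric matrices (must include the
#'   density layer).
#' @param realm Character or factor matrix of realm labels (NA allowed
#'   before [fill_realms()]).
#' @param density_layer Name of the sampling-density layer (default
#'   `"sampling_density"`).
#' @return Object of class `predictor_stack`.
#' @export
predictor_stack <- function(grid, layers, realm = NULL,
                            density_layer = "sampling_density") {
  stopifnot(inherits(grid, "grid_spec"), is.list(layers),
            !is.null(names(layers)), density_layer %in% names(layers))
  dims <- as.integer(c(grid$n_rows, grid$n_cols))
  for (nm in names(layers))
    if (!identical(dim(layers[[nm]]), dims)) stop("layer misaligned: ", nm)
  if (!is.null(realm) && !identical(dim(realm), dims))
    stop("realm layer misaligned")
  structure(list(grid = grid, layers = layers, realm = realm,
                 density_layer = density_layer),
            class = "predictor_stack")
}

#' Screen out collinear predictors
#'
#' Iteratively removes continuous layers until no pair has |Pearson r|
#' above the threshold over unmasked cells: at each step the worst pair
#' is found and the member with the larger variance inflation factor
#' (computed from the correlation matrix of the currently retained
#' layers) is dropped; exact VIF ties drop the later layer in stack
#' order, so the outcome is deterministic. The categorical realm layer
#' and the sampling-density layer are exempt.
#'
#' @param stack A [predictor_stack()].
#' @param threshold Absolute correlation threshold (default 0.7).
#' @return Character vector of retained layer names (including exempt
#'   layers).
#' @export
screen_collinearity <- function(stack, threshold = 0.7) {
  stopifnot(inherits(stack, "predictor_stack"))
  g <- stack$grid
  cand <- setdiff(names(stack$layers), stack$density_layer)
  if (length(cand) >= 2) {
    ok_cells <- g$land_mask & !g$exclusion_mask
    X <- sapply(stack$layers[cand], function(m) m[ok_cells])
    X <- X[stats::complete.cases(X), , drop = FALSE]
    repeat {
      C <- abs(cor(X))
      diag(C) <- 0
      if (max(C) <= threshold) break
      worst <- which(C == max(C), arr.ind = TRUE)[1, ]
      vifs <- tryCatch(diag(solve(cor(X))), error = function(e)
        rep(Inf, ncol(X)))
      drop_i <- if (vifs[worst[1]] > vifs[worst[2]]) worst[1]
                else if (vifs[worst[2]] > vifs[worst[1]]) worst[2]
                else max(worst)
      X <- X[, -drop_i, drop = FALSE]
      if (ncol(X) < 2) break
    }
    cand <- colnames(X)
  }
  c(cand, stack$density_layer)
}

#' Fill unlabeled realm cells by nearest labeled neighbor
#'
#' Assigns each NA land cell the realm of the closest labeled cell
#' (great-circle distance, k = 1), the limiting "most proximal cell"
#' classification used to patch islands and coasts missing from realm
#' polygons.
#'
#' @param realm Character matrix of realm labels with NAs.
#' @param grid The matching [grid_spec()].
#' @return The filled matrix (non-land cells stay NA).
#' @export
fill_realms <- function(realm, grid) {
  lab <- which(!is.na(realm) & grid$land_mask)
  if (!length(lab)) stop("no labeled cells to fill from")
  todo <- which(is.na(realm) & grid$land_mask)
  if (!length(todo)) return(realm)
  cc <- cell_centers(grid)
  unitv <- function(idx) {
    r <- (idx - 1L) %% grid$n_rows + 1L
    cl <- (idx - 1L) %/% grid$n_rows + 1L
    lon <- cc$lon[cl] * pi / 180; lat <- cc$lat[r] * pi / 180
    cbind(cos(lat) * cos(lon), cos(lat) * sin(lon), sin(lat))
  }
  vl <- unitv(lab); vt <- unitv(todo)
  # chord distance is monotone in great-circle distance
  nearest <- max.col(vt %*% t(vl), ties.method = "first")
  realm[todo] <- realm[lab[nearest]]
  realm
}

#' Systematic checkerboard fold assignment
#'
#' Partitions the grid into `block_rows x block_cols` equal spatial
#' blocks (default 10 x 14 = 140) and assigns blocks to `k = 5` folds
#' systematically by row-major block index modulo 5, so horizontally
#' adjacent blocks always land in different folds and every fold gets
#' exactly 28 blocks.
#'
#' @param grid A [grid_spec()].
#' @param block_rows,block_cols Block grid dimensions (defaults 10, 14).
#' @param k Number of folds (default 5).
#' @return Object of class `fold_assignment`: `fold` (integer matrix,
#'   per-cell fold), `block` (per-cell block index), plus the block
#'   dimensions.
#' @export
checkerboard_folds <- function(grid, block_rows = 10, block_cols = 14, k = 5) {
  br <- pmin(ceiling(seq_len(grid$n_rows) / (grid$n_rows / block_rows)),
             block_rows)
  bc <- pmin(ceiling(seq_len(grid$n_cols) / (grid$n_cols / block_cols)),
             block_cols)
  block <- outer(br, bc, function(i, j) (i - 1L) * block_cols + j)
  fold <- (block - 1L) %% k + 1L
  structure(list(fold = fold, block = block, block_rows = block_rows,
                 block_cols = block_cols, k = k),
            class = "fold_assignment")
}

# build the model frame for RF fitting: one row per usable cell
rf_model_frame <- function(stack, response, retained = NULL) {
  g <- stack$grid
  keep <- names(stack$layers)
  if (!is.null(retained)) keep <- intersect(keep, retained)
  ok <- g$land_mask & !g$exclusion_mask & !is.na(response$values)
  for (nm in keep) ok <- ok & !is.na(stack$layers[[nm]])
  if (!is.null(stack$realm)) ok <- ok & !is.na(stack$realm)
  idx <- which(ok)
  df <- as.data.frame(lapply(stack$layers[keep], function(m) m[idx]))
  if (!is.null(stack$realm)) {
    f <- factor(stack$realm[idx])
    oh <- model.matrix(~ f - 1)
    colnames(oh) <- paste0("realm_", levels(f))
    df <- cbind(df, as.data.frame(oh))
  }
  df$.response <- response$values[idx]
  attr(df, "cells") <- idx
  df
}

#' Tune Random Forest complexity by spatial cross-validation
#'
#' For each candidate `mtry` a forest is trained on four checkerboard
#' folds and scored by mean squared error on the held-out fold; the
#' `mtry` with minimum average MSE wins (ties to the smaller value) and
#' the final forest is refit on all data with that setting. Rarity
#' responses are log-transformed first (natural log with an offset of
#' half the smallest positive value, to guard exact zeros).
#'
#' @param stack A [predictor_stack()] (realm already filled).
#' @param response A [div_raster()] of empirical richness or rarity.
#' @param folds A [checkerboard_folds()] assignment.
#' @param mtry_grid Candidate values (default 1:10, capped at the
#'   predictor count).
#' @param n_trees Trees per forest (default 500).
#' @param response_transform `"identity"` or `"log"` (use `"log"` for
#'   rarity).
#' @param retained Layer names kept by [screen_collinearity()]; NULL
#'   uses all layers.
#' @param seed Integer seed (forests and fold scoring are
#'   deterministic given it).
#' @return Object of class `rf_fit`: `model` (final ranger forest),
#'   `mtry`, `mse_table` (per-mtry average MSE), `transform`,
#'   `log_offset`, `retained`, `frame_cells`.
#' @export
tune_mtry <- function(stack, response, folds, mtry_grid = 1:10,
                      n_trees = 500, response_transform = c("identity", "log"),
                      retained = NULL, seed = 1) {
  response_transform <- match.arg(response_transform)
  df <- rf_model_frame(stack, response, retained)
  cells <- attr(df, "cells")
  off <- 0
  if (response_transform == "log") {
    pos <- df$.response[df$.response > 0]
    off <- if (length(pos)) min(pos) / 2 else 1e-12
    df$.response <- log(df$.response + off)
  }
  fold_of <- folds$fold[cells]
  p <- ncol(df) - 1
  mtry_grid <- mtry_grid[mtry_grid <= p]
  mse <- sapply(mtry_grid, function(mt) {
    errs <- sapply(sort(unique(fold_of)), function(f) {
      tr <- df[fold_of != f, , drop = FALSE]
      te <- df[fold_of == f, , drop = FALSE]
      if (!nrow(te) || !nrow(tr)) return(NA_real_)
      fit <- ranger::ranger(dependent.variable.name = ".response", data = tr,
                            num.trees = n_trees, mtry = mt, seed = seed,
                            num.threads = 1)
      mean((predict(fit, te)$predictions - te$.response)^2)
    })
    mean(errs, na.rm = TRUE)
  })
  best <- mtry_grid[which.min(mse)]  # which.min takes the first = smallest mtry
  final <- ranger::ranger(dependent.variable.name = ".response", data = df,
                          num.trees = n_trees, mtry = best, seed = seed,
                          importance = "permutation", num.threads = 1)
  structure(list(model = final, mtry = best,
                 mse_table = data.frame(mtry = mtry_grid, mse = mse),
                 transform = response_transform, log_offset = off,
                 retained = setdiff(names(df), ".response"),
                 frame_cells = cells, seed = seed,
                 metric = response$metric),
            class = "rf_fit")
}

#' Permutation importance of the fitted forest
#'
#' Out-of-bag increase in error when each predictor is permuted,
#' sorted descending (the forest is trained with
#' `importance = "permutation"`).
#'
#' @param fit An [tune_mtry()] result.
#' @return Data frame with columns `predictor`, `importance`.
#' @export
permutation_importance <- function(fit) {
  stopifnot(inherits(fit, "rf_fit"))
  imp <- ranger::importance(fit$model)
  data.frame(predictor = names(sort(imp, decreasing = TRUE)),
             importance = unname(sort(imp, decreasing = TRUE)),
             row.names = NULL)
}

rf_predict_raster <- function(fit, stack, density_override = NULL) {
  g <- stack$grid
  idx <- fit$frame_cells
  keep <- intersect(names(stack$layers), fit$retained)
  df <- as.data.frame(lapply(stack$layers[keep], function(m) m[idx]))
  if (!is.null(density_override))
    df[[stack$density_layer]] <- rep(density_override, length(idx))
  if (!is.null(stack$realm)) {
    f <- factor(stack$realm[idx])
    oh <- model.matrix(~ f - 1)
    colnames(oh) <- paste0("realm_", levels(f))
    df <- cbind(df, as.data.frame(oh))
  }
  missing_cols <- setdiff(fit$retained, names(df))
  for (mc in missing_cols) df[[mc]] <- 0
  pred <- predict(fit$model, df[, fit$retained, drop = FALSE])$predictions
  if (fit$transform == "log") pred <- exp(pred) - fit$log_offset
  v <- matrix(NA_real_, g$n_rows, g$n_cols)
  v[idx] <- pmax(pred, 0)
  div_raster(g, v, fit$metric)
}

#' Project diversity under universally high sampling
#'
#' Predicts the response twice with the fitted forest: once with the
#' observed predictor stack (empirical prediction) and once with the
#' sampling-density layer replaced by the constant 1, the highest
#' observed density (the universal high-sampling counterfactual).
#' Log-transformed responses are back-transformed by exponentiation
#' (monotone, so center locations are unaffected). Diversity centers are
#' recomputed on both surfaces and every cell is classified as exactly
#' one of: `robust` (center in both), `drop` (center only empirically),
#' `enter` (center only counterfactually — the "treasure map" cells), or
#' `noncenter`.
#'
#' @param fit An [tune_mtry()] result whose predictors include the
#'   density layer.
#' @param stack The [predictor_stack()] used for fitting.
#' @param fraction Center area fraction (default 0.10).
#' @return Object of class `counterfactual_result`: `empirical_pred`,
#'   `counterfactual_pred` ([div_raster()]s), `empirical_centers`,
#'   `counterfactual_centers`, `change_class` (character matrix).
#' @export
counterfactual_high_sampling <- function(fit, stack, fraction = 0.10) {
  stopifnot(inherits(fit, "rf_fit"), inherits(stack, "predictor_stack"))
  if (!stack$density_layer %in% fit$retained)
    stop("fitted model does not use the sampling-density layer")
  emp <- rf_predict_raster(fit, stack)
  cf <- rf_predict_raster(fit, stack, density_override = 1)
  ce <- detect_centers(emp, fraction)
  cc <- detect_centers(cf, fraction)
  cls <- matrix("noncenter", stack$grid$n_rows, stack$grid$n_cols)
  cls[ce$member & cc$member] <- "robust"
  cls[ce$member & !cc$member] <- "drop"
  cls[!ce$member & cc$member] <- "enter"
  structure(list(empirical_pred = emp, counterfactual_pred = cf,
                 empirical_centers = ce, counterfactual_centers = cc,
                 change_class = cls),
            class = "counterfactual_result")
}

#' Robustness fractions of diversity centers under the counterfactual
#'
#' Area fractions of the center-change classification: `robust` and
#' `drop` relative to the empirical center area (they sum to 1), `enter`
#' relative to the counterfactual center area.
#'
#' @param result A [counterfactual_high_sampling()] result.
#' @return Named numeric vector `c(robust, drop, enter)`.
#' @export
robustness_fraction <- function(result) {
  stopifnot(inherits(result, "counterfactual_result"))
  areas <- spherical_cell_areas(result$empirical_pred$grid)
  a_emp <- sum(areas[result$empirical_centers$member])
  a_cf <- sum(areas[result$counterfactual_centers$member])
  c(robust = sum(areas[result$change_class == "robust"]) / a_emp,
    drop = sum(areas[result$change_class == "drop"]) / a_emp,
    enter = sum(areas[result$change_class == "enter"]) / a_cf)
}
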