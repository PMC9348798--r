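bias_stack <- function(seed = 1) {
  g <- grid_spec(120, 0, 60, -30, 30)  # 30 x 30 cells, all land
  set.seed(seed)
  n <- g$n_rows * g$n_cols
  layers <- list(x1 = matrix(smooth_field(g, seed + 1), g$n_rows),
                 x2 = matrix(smooth_field(g, seed + 2), g$n_rows),
                 sampling_density = matrix(runif(n), g$n_rows))
  realm <- matrix(rep(c("east", "west"), each = n / 2), g$n_rows)
  list(grid = g,
       stack = predictor_stack(g, layers, realm = realm))
}

test_that("collinearity screening drops one of each over-correlated pair", {
  b <- bias_stack()
  g <- b$grid
  # identical layers: exactly one dropped, density exempt
  dup <- predictor_stack(g, list(a = b$stack$layers$x1,
                                 b = b$stack$layers$x1,
                                 sampling_density = b$stack$layers$sampling_density))
  kept <- screen_collinearity(dup, 0.7)
  expect_equal(sum(c("a", "b") %in% kept), 1L)
  expect_true("sampling_density" %in% kept)
  # uncorrelated layers all survive
  ind <- predictor_stack(g, list(a = b$stack$layers$x1,
                                 c = matrix(rnorm(g$n_rows * g$n_cols), g$n_rows),
                                 sampling_density = b$stack$layers$sampling_density))
  expect_setequal(screen_collinearity(ind, 0.7),
                  c("a", "c", "sampling_density"))
  # planted structure A ~ B, both independent of C: keep one of {A, B} plus C
  set.seed(4)
  A <- matrix(rnorm(g$n_rows * g$n_cols), g$n_rows)
  B <- A + matrix(rnorm(g$n_rows * g$n_cols, 0, 0.1), g$n_rows)
  C <- matrix(rnorm(g$n_rows * g$n_cols), g$n_rows)
  st <- predictor_stack(g, list(A = A, B = B, C = C,
                                sampling_density = b$stack$layers$sampling_density))
  kept2 <- screen_collinearity(st, 0.7)
  expect_equal(sum(c("A", "B") %in% kept2), 1L)
  expect_true("C" %in% kept2)
  expect_identical(kept2, screen_collinearity(st, 0.7))  # deterministic
})

test_that("realm filling assigns each empty cell its nearest labeled neighbor", {
  g <- grid_spec(120, 0, 20, 0, 20)  # 10 x 10
  realm <- matrix(NA_character_, 10, 10)
  realm[5, 5] <- "only"
  filled <- fill_realms(realm, g)
  expect_true(all(filled == "only"))
  # east/west labels split at the equidistance boundary (Voronoi oracle)
  realm2 <- matrix(NA_character_, 10, 10)
  realm2[, 1] <- "west"; realm2[, 10] <- "east"
  filled2 <- fill_realms(realm2, g)
  cc <- cell_centers(g)
  oracle <- ifelse(abs(cc$lon - cc$lon[1]) <= abs(cc$lon - cc$lon[10]),
                   "west", "east")
  for (col in 1:10) expect_equal(unique(filled2[, col]), oracle[col])
  # no NA input is an identity
  expect_identical(fill_realms(filled2, g), filled2)
  expect_error(fill_realms(matrix(NA_character_, 10, 10), g), "labeled")
})

test_that("checkerboard folds partition 140 blocks into 5 folds of 28", {
  g <- grid_spec(60, -180, 180, -60, 60)
  f <- checkerboard_folds(g)
  expect_equal(length(unique(as.vector(f$block))), 140L)
  expect_equal(as.integer(table(unique(cbind(as.vector(f$block),
                                             as.vector(f$fold)))[, 2])),
               rep(28L, 5))
  # horizontally adjacent blocks never share a fold
  blocks <- unique(cbind(block = as.vector(f$block), fold = as.vector(f$fold)))
  bl <- blocks[order(blocks[, 1]), ]
  for (i in seq_len(139)) {
    same_row <- ((bl[i, 1] - 1) %/% 14) == ((bl[i + 1, 1] - 1) %/% 14)
    if (same_row) expect_false(bl[i, 2] == bl[i + 1, 2])
  }
  # every cell assigned exactly one fold
  expect_true(all(f$fold %in% 1:5))
  expect_equal(dim(f$fold), c(g$n_rows, g$n_cols))
})

test_that("mtry tuning finds signal, stays honest on noise, and is deterministic", {
  b <- bias_stack(7)
  g <- b$grid
  folds <- checkerboard_folds(g, block_rows = 5, block_cols = 6, k = 5)
  # response is an exact function of one predictor: CV MSE << variance
  resp <- div_raster(g, 3 * b$stack$layers$x1 + 10)
  fit <- tune_mtry(b$stack, resp, folds, mtry_grid = c(1, 2, 4),
                   n_trees = 150, seed = 3)
  expect_lt(min(fit$mse_table$mse), 0.2 * var(as.vector(resp$values)))
  # selected mtry has the minimum CV MSE by construction
  expect_equal(fit$mtry, fit$mse_table$mtry[which.min(fit$mse_table$mse)])
  # pure-noise response: no mtry beats the mean predictor meaningfully
  set.seed(5)
  noise <- div_raster(g, matrix(rnorm(g$n_rows * g$n_cols), g$n_rows))
  fitn <- tune_mtry(b$stack, noise, folds, mtry_grid = c(1, 4),
                    n_trees = 150, seed = 3)
  expect_gt(min(fitn$mse_table$mse), 0.8 * var(as.vector(noise$values)))
  # same seed, same result
  fit2 <- tune_mtry(b$stack, resp, folds, mtry_grid = c(1, 2, 4),
                    n_trees = 150, seed = 3)
  expect_identical(fit2$mtry, fit$mtry)
  expect_equal(fit2$mse_table, fit$mse_table)
})

test_that("permutation importance ranks the sole informative predictor first", {
  b <- bias_stack(9)
  folds <- checkerboard_folds(b$grid, block_rows = 5, block_cols = 6, k = 5)
  resp <- div_raster(b$grid, 4 * b$stack$layers$x2 + 1)
  fit <- tune_mtry(b$stack, resp, folds, mtry_grid = 2, n_trees = 200, seed = 1)
  imp <- permutation_importance(fit)
  expect_equal(imp$predictor[1], "x2")
  # uninformative predictors sit near zero importance
  expect_lt(imp$importance[imp$predictor == "x1"],
            0.05 * imp$importance[1])
})

test_that("a uniform sampling-density layer makes the counterfactual an identity", {
  b <- bias_stack(11)
  st <- b$stack
  st$layers$sampling_density[] <- 1
  resp <- div_raster(b$grid, 2 * st$layers$x1 + st$layers$x2 + 5)
  folds <- checkerboard_folds(b$grid, block_rows = 5, block_cols = 6, k = 5)
  fit <- tune_mtry(st, resp, folds, mtry_grid = 2, n_trees = 100, seed = 2)
  cf <- counterfactual_high_sampling(fit, st)
  expect_identical(cf$empirical_pred$values, cf$counterfactual_pred$values)
  expect_false(any(cf$change_class %in% c("drop", "enter")))
  rf <- robustness_fraction(cf)
  expect_equal(unname(rf["robust"]), 1)
  # every cell falls in exactly one class
  expect_true(all(cf$change_class %in% c("noncenter", "robust", "drop", "enter")))
})

test_that("robustness fractions follow the 3-cell hand enumeration", {
  # construct a result with equal-area cells: 1 robust, 1 drop, 1 enter
  g <- grid_spec(60, 0, 3, -0.5, 0.5)
  mk <- function(cells) {
    m <- matrix(FALSE, 1, 3); m[cells] <- TRUE
    structure(list(grid = g, member = m, fraction = 0.1,
                   realized_area_fraction = 0.1), class = "center_mask")
  }
  cls <- matrix(c("robust", "drop", "enter"), 1, 3)
  res <- structure(list(empirical_pred = div_raster(g, matrix(1, 1, 3)),
                        counterfactual_pred = div_raster(g, matrix(1, 1, 3)),
                        empirical_centers = mk(c(1, 2)),
                        counterfactual_centers = mk(c(1, 3)),
                        change_class = cls),
                   class = "counterfactual_result")
  rf <- robustness_fraction(res)
  expect_equal(unname(rf), c(0.5, 0.5, 0.5))
})
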