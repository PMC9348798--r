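test_that("spearman congruence matches its analytic anchors", {
  g <- flat_grid()
  r <- div_raster(g, smooth_field(g, seed = 5) + 2)
  expect_equal(spearman_between(r, r), 1)
  neg <- r; neg$values <- -r$values
  expect_equal(spearman_between(r, neg), -1)
  # calibrated companion taxon
  comp <- generate_companion_taxa(r, 0.75, seed = 9)
  expect_lt(abs(spearman_between(r, comp) - 0.75), 0.05)
  # invariant under strictly monotone transforms
  tr <- r; tr$values <- exp(3 * r$values)
  expect_equal(spearman_between(tr, comp), spearman_between(r, comp))
})

test_that("center overlap is an area fraction with equal-area symmetry", {
  g <- flat_grid()
  set.seed(6)
  a <- detect_centers(div_raster(g, matrix(runif(g$n_rows * g$n_cols),
                                           g$n_rows)), 0.10)
  expect_equal(overlap_fraction(a, a), 1)
  b <- detect_centers(div_raster(g, matrix(runif(g$n_rows * g$n_cols),
                                           g$n_rows)), 0.10)
  # brute-force area oracle
  areas <- spherical_cell_areas(g)
  oracle <- sum(areas[a$member & b$member]) / sum(areas[a$member])
  expect_equal(overlap_fraction(a, b), oracle)
  expect_true(overlap_fraction(a, b) >= 0 && overlap_fraction(a, b) <= 1)
  # equal-area masks make the statistic symmetric (equal denominators)
  expect_equal(overlap_fraction(a, b) * sum(areas[a$member]),
               overlap_fraction(b, a) * sum(areas[b$member]))
  # disjoint masks
  d1 <- a; d1$member[] <- FALSE; d1$member[1:10, 1:10] <- TRUE
  d2 <- a; d2$member[] <- FALSE; d2$member[50:60, 50:60] <- TRUE
  expect_equal(overlap_fraction(d1, d2), 0)
})

test_that("congruence tables are symmetric with unit diagonal", {
  g <- flat_grid()
  r1 <- div_raster(g, smooth_field(g, seed = 1) + 2)
  r2 <- generate_companion_taxa(r1, 0.6, seed = 2)
  r3 <- generate_companion_taxa(r1, -0.3, seed = 3)
  tab <- congruence_table(list(a = r1, b = r2, c = r3))
  expect_equal(diag(tab$rho_matrix), c(a = 1, b = 1, c = 1))
  expect_equal(tab$rho_matrix, t(tab$rho_matrix))
  expect_equal(diag(tab$overlap_matrix), c(a = 1, b = 1, c = 1))
})

test_that("community observations bound and regress on modeled richness", {
  g <- flat_grid()
  set.seed(11)
  model <- div_raster(g, matrix(5 + 4 * runif(g$n_rows * g$n_cols), g$n_rows))
  cc <- cell_centers(g)
  idx <- sample(g$n_rows * g$n_cols, 300)
  row <- (idx - 1) %% g$n_rows + 1; col <- (idx - 1) %/% g$n_rows + 1
  # observations equal to the model reproduce R^2 = 1 with no violations
  obs <- data.frame(lon = cc$lon[col], lat = cc$lat[row], study = "s1",
                    richness = model$values[idx])
  out <- suppressWarnings(upper_bound_comparison(model, obs, factors = 1))
  expect_equal(out$r_squared, 1)
  expect_equal(out$n_violations, 0L)
  # scaled observations with vanishing noise still give R^2 -> 1
  obs2 <- obs; obs2$richness <- 0.5 * obs$richness + rnorm(300, 0, 1e-6)
  expect_gt(upper_bound_comparison(model, obs2, factors = 1)$r_squared, 0.999)
  # community samples drawn below the true value rarely violate the bound
  obs3 <- obs
  obs3$richness <- obs$richness * runif(300, 0.3, 0.98)
  out3 <- upper_bound_comparison(model, obs3, factors = c(1, 2, 5))
  expect_true(all(out3$n_violations / out3$n_cells <= 0.05))
})

test_that("per-study maxima never sum richness across studies", {
  g <- flat_grid()
  model <- div_raster(g, matrix(10, g$n_rows, g$n_cols))
  cc <- cell_centers(g)
  obs <- data.frame(lon = cc$lon[c(5, 5, 5, 20, 20, 40, 60)],
                    lat = cc$lat[c(5, 5, 5, 20, 20, 40, 60)],
                    study = c("s1", "s1", "s2", "s1", "s2", "s1", "s1"),
                    richness = c(4, 6, 7, 5, 5, 8, 3))
  out <- upper_bound_comparison(model, obs, factors = 2)
  # max per cell is 7 on the first cell (never 4 + 6 + 7 across studies),
  # so nothing exceeds the constant model value of 10
  expect_equal(out$n_violations, 0L)
  expect_equal(out$n_cells, 4L)
})

test_that("protected coverage dissolves overlap and matches constructed geometry", {
  g <- grid_spec(30, 0, 10, 0, 10)
  v <- matrix(0, g$n_rows, g$n_cols); v[1:4, ] <- 1
  centers <- detect_centers(div_raster(g, v), 0.18)
  # protection covering everything
  world_poly <- list(geo_polygon(list(cbind(c(-1, 11, 11, -1),
                                            c(-1, -1, 11, 11)))))
  expect_equal(protected_coverage(centers, world_poly)$protected_fraction, 1)
  # no protection at all
  far <- list(geo_polygon(list(cbind(c(20, 21, 21, 20), c(0, 0, 1, 1)))))
  expect_equal(protected_coverage(centers, far)$protected_fraction, 0)
  # two identical overlapping squares over the same half: exactly 0.5 by area
  member_rows <- which(apply(centers$member, 1, any))
  lat_split <- 10 - max(member_rows) / 2 +
    (max(member_rows) - min(member_rows) + 1) / 4
  half <- geo_polygon(list(cbind(c(-1, 11, 11, -1),
                                 c(lat_split, lat_split, 11, 11))))
  two <- list(half, geo_polygon(list(half$rings[[1]])))
  cov <- protected_coverage(centers, two)$protected_fraction
  areas <- spherical_cell_areas(g)
  cc <- cell_centers(g)
  manual <- sum(areas[centers$member &
                        matrix(cc$lat, g$n_rows, g$n_cols) > lat_split]) /
    sum(areas[centers$member])
  expect_equal(cov, manual)
  expect_gt(cov, 0.4); expect_lt(cov, 0.6)
})

test_that("dissolving protection polygons is idempotent", {
  w <- test_world()
  polys <- generate_protected_areas(w$grid, 0.08, seed = 3)
  once <- dissolve_polygons(polys)
  twice <- dissolve_polygons(once)
  expect_identical(twice, once)
})
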