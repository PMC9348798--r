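test_that("window incidence counts distinct cells per species", {
  win <- 1:10
  occ <- list(sp1 = c(1, 2, 3))
  f <- window_incidence(occ, win)
  expect_equal(f$S_obs, 1L)
  expect_equal(unname(f$Y), 3L)
  expect_equal(f$Q1, 0L); expect_equal(f$Q2, 0L)
  # two singletons
  f2 <- window_incidence(list(a = 4, b = 9), win)
  expect_equal(f2$Q1, 2L); expect_equal(f2$U, 2L)
  # hand tally: planted incidences {1, 1, 2, 3, 7}
  occ3 <- list(a = 1, b = 2, c = c(3, 4), d = c(5, 6, 7), e = c(1:7))
  f3 <- window_incidence(occ3, win)
  expect_equal(f3$S_obs, 5L)
  expect_equal(f3$Q1, 2L); expect_equal(f3$Q2, 1L); expect_equal(f3$U, 14L)
  # records outside the window are ignored; repeated cells count once
  f4 <- window_incidence(list(a = c(1, 1, 99)), win)
  expect_equal(unname(f4$Y), 1L)
})

test_that("chao2 matches its closed form and never falls below S_obs", {
  # hand evaluation: S_obs 5, Q1 2, Q2 1, T 10 -> 5 + (9/10) * 4/2 = 6.8
  f <- list(T = 10, S_obs = 5, Q1 = 2, Q2 = 1, U = 14)
  est <- chao2_estimate(f)
  expect_equal(est$S_hat, 6.8)
  # no singletons: estimate equals the observation
  expect_equal(chao2_estimate(list(T = 10, S_obs = 4, Q1 = 0, Q2 = 2,
                                   U = 9))$S_hat, 4)
  # U = 0 -> NA
  expect_true(is.na(chao2_estimate(list(T = 5, S_obs = 0, Q1 = 0, Q2 = 0,
                                        U = 0))$S_hat))
  # brute-force formula oracle over 1,000 random inputs
  set.seed(19)
  for (i in 1:1000) {
    T <- sample(2:60, 1)
    Y <- sample(1:min(T, 8), sample(1:12, 1), replace = TRUE)
    f <- list(T = T, S_obs = length(Y), Q1 = sum(Y == 1), Q2 = sum(Y == 2),
              U = sum(Y))
    oracle <- if (f$Q2 > 0)
      f$S_obs + (T - 1) / T * f$Q1^2 / (2 * f$Q2)
    else f$S_obs + (T - 1) / T * f$Q1 * (f$Q1 - 1) / 2
    est <- chao2_estimate(f)
    expect_identical(est$S_hat, oracle)
    expect_gte(est$S_hat, f$S_obs)
    expect_true(est$coverage_hat >= 0 && est$coverage_hat <= 1)
  }
})

test_that("chao2 agrees with the standard community-ecology implementation", {
  set.seed(23)
  # incidence matrix: sites x species
  mat <- matrix(rbinom(30 * 12, 1, 0.25), nrow = 30)
  mat <- mat[, colSums(mat) > 0, drop = FALSE]
  Y <- colSums(mat)
  f <- list(T = 30, S_obs = length(Y), Q1 = sum(Y == 1), Q2 = sum(Y == 2),
            U = sum(Y))
  ours <- chao2_estimate(f)$S_hat
  ref <- vegan::specpool(mat)$chao
  expect_equal(ours, ref, tolerance = 1e-8)
})

test_that("adding doubletons never increases the estimate", {
  for (Q2 in 1:10) {
    a <- chao2_estimate(list(T = 30, S_obs = 20, Q1 = 6, Q2 = Q2, U = 60))
    b <- chao2_estimate(list(T = 30, S_obs = 20, Q1 = 6, Q2 = Q2 + 1, U = 62))
    expect_gte(a$S_hat, b$S_hat)
  }
})

test_that("window filters drop single-cell and all-singleton windows", {
  # all incidences in one cell
  f1 <- window_incidence(list(a = 5, b = 5, c = 5), 1:10)
  expect_false(window_filters(f1))
  # every incidence a singleton: Q1 == U
  f2 <- window_incidence(list(a = 1, b = 2, c = 3), 1:10)
  expect_equal(f2$Q1, f2$U)
  expect_false(window_filters(f2))
  # two occupied cells with a repeated species passes both rules
  f3 <- window_incidence(list(a = c(1, 2), b = 1), 1:10)
  expect_true(window_filters(f3))
})

test_that("the moving-window map is exact on exhaustively sampled worlds", {
  g <- grid_spec(120, 0, 40, 0, 40)  # 20 x 20
  # one widespread species observed in every cell: constant map of 1
  occ <- list(sp1 = seq_len(g$n_rows * g$n_cols))
  mw <- moving_window_map(occ, g, window_cells = 10, stride = 5)
  expect_true(all(mw$raster$values == 1, na.rm = TRUE))
  expect_true(all(mw$windows$included))
  expect_true(all(mw$windows$S_hat == 1))
  # exhaustive sampling: S_hat equals true window richness (no singletons
  # when every species occupies >= 3 cells)
  set.seed(31)
  occ2 <- lapply(1:8, function(k) sample(seq_len(400), 12))
  names(occ2) <- paste0("sp", 1:8)
  mw2 <- moving_window_map(occ2, g, window_cells = 20, stride = 20)
  truth <- length(occ2)
  got <- mw2$windows$S_hat[mw2$windows$included]
  expect_equal(got, rep(truth, length(got)))
  # filtered windows leave NA footprints
  occ3 <- list(a = 1L)  # single occupied cell anywhere
  mw3 <- moving_window_map(occ3, g, window_cells = 10, stride = 10)
  expect_true(all(is.na(mw3$raster$values)))
})

test_that("window estimates track true window richness on the synthetic world", {
  # the estimator targets the gamma diversity of each window, so the
  # recovery check compares per-window estimates with the true number
  # of species occupying any cell of the same window
  w <- test_world()
  g <- w$grid
  rec <- simulate_collection(w$pool, w$bias, effort = 4,
                             noise = noise_config(0, 0, 0, 0, 0),
                             gazetteer = w$gazetteer, seed = 13)
  rc <- cell_at(g, rec$true_lon, rec$true_lat)
  occ <- lapply(split(cell_index(g, rc$row, rc$col), rec$species_id), unique)
  mw <- moving_window_map(occ, g, window_cells = 10, stride = 5)
  truth_occ <- lapply(w$pool, function(sp) sp$cells)
  names(truth_occ) <- vapply(w$pool, function(sp) sp$species_id, "")
  wins <- mw$windows[mw$windows$included, ]
  true_rich <- vapply(seq_len(nrow(wins)), function(i) {
    rr <- wins$row0[i]:min(g$n_rows, wins$row0[i] + 9)
    cc <- wins$col0[i]:min(g$n_cols, wins$col0[i] + 9)
    wcells <- as.vector(outer(rr, (cc - 1L) * g$n_rows, "+"))
    sum(vapply(truth_occ, function(cells) length(intersect(cells, wcells)) > 0,
               TRUE))
  }, 0)
  expect_gt(nrow(wins), 30)
  expect_gte(cor(wins$S_hat, true_rich, method = "spearman"), 0.6)
  # estimates never exceed observation by less than zero, and sampling
  # completeness stays in [0, 1]
  expect_true(all(wins$S_hat >= wins$S_obs))
  expect_true(all(wins$coverage >= 0 & wins$coverage <= 1))
})
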