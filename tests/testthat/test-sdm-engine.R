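test_that("sampling density peaks at the data, is rescaled to max 1, and respects water", {
  w <- test_world()
  g <- w$grid
  cc <- cell_centers(g)
  land1 <- which(g$land_mask, arr.ind = TRUE)[1, ]
  pt <- cbind(cc$lon[land1[2]], cc$lat[land1[1]])
  d1 <- build_sampling_density(pt, g)
  expect_equal(max(d1$density), 1)
  expect_equal(unname(which(d1$density == 1, arr.ind = TRUE)[1, ]),
               unname(land1))
  expect_true(all(d1$density[!g$land_mask] == 0))
  # dense uniform points give a near-flat interior
  gg <- grid_spec(60, 0, 40, 0, 40)
  set.seed(2)
  pts <- cbind(runif(4000, 0, 40), runif(4000, 0, 40))
  dflat <- build_sampling_density(pts, gg, bandwidth = 8)
  interior <- dflat$density[10:30, 10:30]
  expect_gt(min(interior) / max(interior), 0.5)
})

test_that("background sampling honors extent size and density weights", {
  set.seed(1)
  # small extents are assigned in full
  expect_equal(sample_background_cells(1:500, n = 10000), 1:500)
  # same seed reproduces the sample
  dens <- matrix(runif(40000), 200, 200)
  s1 <- sample_background_cells(1:20000, dens, n = 10000, seed = 5)
  s2 <- sample_background_cells(1:20000, dens, n = 10000, seed = 5)
  expect_identical(s1, s2)
  # density concentrated in one half draws proportionally
  dens2 <- matrix(0.05, 200, 200)
  dens2[, 1:100] <- 1
  s <- sample_background_cells(1:40000, dens2, n = 10000, seed = 7)
  west <- mean(s <= 20000)
  expect_lt(abs(west - 1 / 1.05), 0.02)
  # zero density falls back to uniform with a warning
  expect_warning(sample_background_cells(1:20000, matrix(0, 200, 100),
                                         n = 10000, seed = 1), "uniform")
})

test_that("feature expansion matches the class definitions", {
  bg <- cbind(a = rnorm(500), b = rnorm(500, 5, 2))
  sL <- feature_spec(bg, "L")
  expect_equal(ncol(build_features(bg, sL)), 2L)
  sLQ <- feature_spec(bg, "LQ")
  expect_equal(ncol(build_features(bg, sLQ)), 4L)
  sH <- feature_spec(bg, "H", hinge_knots = 8)
  expect_equal(ncol(build_features(bg, sH)), 16L)
  sLQH <- feature_spec(bg, "LQH", hinge_knots = 8)
  expect_equal(ncol(build_features(bg, sLQH)), 20L)
  # hinge definition max(0, x - k)
  expect_equal(pmax(0, c(-1, 0, 2) - 0), c(0, 0, 2))
  # constant variables are dropped with a warning
  expect_warning(feature_spec(cbind(a = rnorm(100), b = rep(1, 100)), "L"),
                 "constant")
})

test_that("the penalized fit recovers gradient direction and shrinks under penalty", {
  fx <- sdm_fixture()
  spec <- feature_spec(fx$bg, "L")
  Xb <- build_features(fx$bg, spec)
  Xp <- build_features(fx$pres, spec)
  fit <- fit_pb_model(Xp, Xb, spec, m = 1)
  # oracle: logistic regression of presence vs background has the same sign
  oracle <- glm(y ~ x, family = binomial,
                data = data.frame(y = rep(1:0, c(nrow(fx$pres), nrow(fx$bg))),
                                  x = c(fx$pres[, 1], fx$bg[, 1])))
  expect_equal(sign(fit$beta[1]), sign(coef(oracle)["x"]), ignore_attr = TRUE)
  # enormous penalty gives the null model
  expect_equal(fit_pb_model(Xp, Xb, spec, m = 1e8)$n_nonzero, 0L)
  # doubling the multiplier never increases the nonzero count (checked
  # empirically over the tuning grid)
  spec2 <- feature_spec(fx$bg, "LQH")
  Xb2 <- build_features(fx$bg, spec2)
  Xp2 <- build_features(fx$pres, spec2)
  nz <- vapply(c(1, 2, 4, 8), function(m)
    fit_pb_model(Xp2, Xb2, spec2, m = m)$n_nonzero, 0L)
  expect_true(all(diff(nz) <= 0))
})

test_that("cloglog predictions are a bounded increasing transform of the linear predictor", {
  fx <- sdm_fixture()
  spec <- feature_spec(fx$bg, "L")
  fit <- fit_pb_model(build_features(fx$pres, spec),
                      build_features(fx$bg, spec), spec, m = 1)
  x <- matrix(seq(-3, 3, 0.1), ncol = 1)
  s <- predict_cloglog(fit, x)
  expect_true(all(s > 0 & s < 1))
  expect_true(all(diff(s) * sign(fit$beta[1]) >= 0))
  # equal eta gives equal suitability; null model is constant
  null <- fit_pb_model(build_features(fx$pres, spec),
                       build_features(fx$bg, spec), spec, m = 1e8)
  expect_equal(length(unique(predict_cloglog(null, x))), 1L)
})

test_that("fold partitioning switches from jackknife to k = 5 at 25 localities", {
  f24 <- partition_folds(24, seed = 1)
  expect_equal(f24$kind, "loo")
  expect_equal(f24$k, 24L)
  expect_equal(f24$assignment, 1:24)
  f25 <- partition_folds(25, seed = 1)
  expect_equal(f25$kind, "random_k")
  expect_equal(as.integer(table(f25$assignment)), rep(5L, 5))
  expect_identical(partition_folds(40, seed = 3)$assignment,
                   partition_folds(40, seed = 3)$assignment)
  expect_error(partition_folds(4), ">= 5")
})

test_that("evaluation metrics behave at their analytic anchors", {
  # perfect separation gives AUC 1; random scores give ~0.5
  expect_equal(rank_auc(6:10, 1:5), 1)
  set.seed(8)
  expect_lt(abs(rank_auc(runif(2000), runif(2000)) - 0.5), 0.05)
  # training-set omission at the 10th percentile threshold is ~0.10
  fx <- sdm_fixture(n_pres = 100)
  spec <- feature_spec(fx$bg, "L")
  fit <- fit_pb_model(build_features(fx$pres, spec),
                      build_features(fx$bg, spec), spec, m = 1)
  train_suit <- predict_cloglog(fit, fx$pres)
  thr <- quantile(train_suit, 0.10, names = FALSE)
  expect_lt(abs(mean(train_suit < thr) - 0.10), 1 / length(train_suit) + 1e-9)
})

test_that("candidate selection applies the sequential filters deterministically", {
  cand <- data.frame(classes = c("L", "LQ", "H", "LQH"), m = c(1, 1, 2, 2),
                     or10 = c(0.2, 0.1, 0.1, 0.1),
                     auc_val = c(0.9, 0.7, 0.8, 0.8),
                     cbi = c(0.5, 0.5, 0.5, 0.5),
                     n_nonzero = c(1, 2, 3, 1))
  # min or10, then max auc: rows 3 and 4 tie on auc, min n_nonzero -> row 4
  expect_equal(select_from_candidates(cand), 4L)
  # auc tie-break alone
  cand2 <- cand; cand2$n_nonzero <- 2
  expect_equal(select_from_candidates(cand2), 3L)
  # cbi filter removes all -> fallback sentinel
  cand3 <- cand; cand3$cbi <- c(0, -0.2, NA, 0)
  expect_true(is.na(select_from_candidates(cand3)))
  # single survivor is selected regardless of its metrics
  cand4 <- cand; cand4$cbi <- c(0.1, 0, 0, 0)
  expect_equal(select_from_candidates(cand4), 1L)
  # order invariance
  perm <- c(3, 1, 4, 2)
  expect_equal(perm[select_from_candidates(cand[perm, ])],
               select_from_candidates(cand))
})

test_that("tuning recovers a synthetic suitability gradient", {
  set.seed(14)
  n_bg <- 3000
  bg <- matrix(runif(n_bg, -2, 2), ncol = 1, dimnames = list(NULL, "env_1"))
  p_true <- 1 / (1 + exp(-3 * bg[, 1]))  # true occupancy probability
  pres <- matrix(bg[sample(n_bg, 120, prob = p_true), 1], ncol = 1,
                 dimnames = list(NULL, "env_1"))
  sel <- tune_and_select(pres, bg, classes = c("L", "LQ"),
                         multipliers = c(1, 2), seed = 2)
  expect_s3_class(sel, "sdm_selection")
  suit <- predict_cloglog(sel$model, bg)
  expect_gte(cor(suit, p_true, method = "spearman"), 0.7)
})
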