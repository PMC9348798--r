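#' Build the global sampling-density surface
#'
#' Gaussian kernel density of all occurrence localities (duplicates
#' pooled to unique coordinates), evaluated at cell centers, with water
#' removed and rescaled so the maximum over land is exactly 1. The
#' surface doubles as a proxy for collection plus taxonomic effort: the
#' background sampler draws from it so that models contrast presences
#' against availability *with the same spatial bias*, and the Random
#' Forest counterfactual later sets it to 1 everywhere.
#'
#' @param points `n x 2` matrix of occurrence (lon, lat) for all species.
#' @param grid A [grid_spec()].
#' @param bandwidth Optional kernel bandwidth (degrees, length 1 or 2);
#'   defaults to the normal reference rule with a floor of one cell.
#' @return A `bias_field` (see [make_bias_field()]).
#' @export
build_sampling_density <- function(points, grid, bandwidth = NULL) {
  pts <- unique(as.matrix(points)[, 1:2, drop = FALSE])
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (nrow(pts) < 1) stop("need at least one occurrence")
  step <- grid_step(grid)
  if (is.null(bandwidth)) {
    bw <- c(tryCatch(MASS::bandwidth.nrd(pts[, 1]), error = function(e) 0),
            tryCatch(MASS::bandwidth.nrd(pts[, 2]), error = function(e) 0))
    bw[!is.finite(bw)] <- 0
    bandwidth <- pmax(bw, 4 * step)
  }
  bandwidth <- rep(bandwidth, length.out = 2)
  k <- MASS::kde2d(pts[, 1], pts[, 2], h = bandwidth,
                   n = c(grid$n_cols, grid$n_rows),
                   lims = c(grid$lon_min + step / 2, grid$lon_max - step / 2,
                            grid$lat_min + step / 2, grid$lat_max - step / 2))
  # kde2d: z[i, j] at (x[i], y[j]), y increasing; our rasters are north-up
  d <- t(k$z)[grid$n_rows:1, , drop = FALSE]
  d[!grid$land_mask] <- 0
  mx <- max(d)
  if (mx <= 0) stop("density is zero everywhere on land")
  structure(list(grid = grid, density = d / mx), class = "bias_field")
}

#' Sample background cells proportional to sampling density
#'
#' Species whose study extent holds fewer than `n` cells receive the
#' full extent as background; larger extents are sampled with
#' replacement with probability proportional to the density surface
#' (uniform, with a warning, if the density is zero over the whole
#' extent).
#'
#' @param extent_cells Cell indices of the study extent (the species'
#'   buffered hull).
#' @param density Density matrix (from a `bias_field`), or NULL for
#'   uniform sampling.
#' @param n Number of background points (default 10000).
#' @param seed Integer seed.
#' @return Integer vector of background cell indices (possibly with
#'   repeats on the sampled branch).
#' @export
sample_background_cells <- function(extent_cells, density = NULL, n = 10000,
                                    seed = 1) {
  if (!length(extent_cells)) stop("extent has no cells")
  if (length(extent_cells) < n) return(extent_cells)
  set.seed(seed)
  p <- if (is.null(density)) rep(1, length(extent_cells))
       else density[extent_cells]
  if (all(p <= 0)) {
    warning("density is zero over the extent; sampling uniformly")
    p <- rep(1, length(extent_cells))
  }
  sample(extent_cells, n, replace = TRUE, prob = p)
}

#' Fit a feature specification on background data
#'
#' Defines the model's transformed feature space: linear features are
#' background-standardized variables, quadratic features their squares,
#' and hinge features forward hinges `max(0, x - k)` with knots at
#' equally spaced quantiles of the background values. Class labels
#' follow the usual shorthand: `"L"`, `"LQ"`, `"H"`, `"LQH"`.
#'
#' @param bg_env Background matrix (cells x variables, raw scale).
#' @param classes One of `"L"`, `"LQ"`, `"H"`, `"LQH"`.
#' @param hinge_knots Knots per variable (default 8).
#' @return Object of class `feature_spec`.
#' @export
feature_spec <- function(bg_env, classes = "LQH", hinge_knots = 8) {
  classes <- match.arg(classes, c("L", "LQ", "H", "LQH"))
  if (hinge_knots < 2) stop("hinge_knots must be >= 2")
  bg_env <- as.matrix(bg_env)
  mu <- colMeans(bg_env)
  s <- apply(bg_env, 2, sd)
  keep <- s > 1e-10
  if (!all(keep)) {
    warning("dropping constant variable(s): ",
            paste(colnames(bg_env)[!keep], collapse = ", "))
    mu <- mu[keep]; s <- s[keep]
  }
  z <- sweep(sweep(bg_env[, keep, drop = FALSE], 2, mu), 2, s, "/")
  knots <- NULL
  if (classes %in% c("H", "LQH")) {
    qs <- seq(0, 1, length.out = hinge_knots + 2)[2:(hinge_knots + 1)]
    knots <- apply(z, 2, quantile, probs = qs, names = FALSE)
    if (is.null(dim(knots))) knots <- matrix(knots, nrow = hinge_knots)
  }
  structure(list(classes = classes, hinge_knots = hinge_knots,
                 mean = mu, sd = s, vars = which(keep), knots = knots),
            class = "feature_spec")
}

#' Expand raw environment values into model features
#'
#' @param values Matrix of raw environment values (rows = cells or
#'   points, columns = variables in the order the spec was fitted on).
#' @param spec A [feature_spec()].
#' @return Numeric feature matrix.
#' @export
build_features <- function(values, spec) {
  stopifnot(inherits(spec, "feature_spec"))
  values <- as.matrix(values)
  z <- sweep(sweep(values[, spec$vars, drop = FALSE], 2, spec$mean),
             2, spec$sd, "/")
  nv <- ncol(z)
  out <- list()
  if (spec$classes %in% c("L", "LQ", "LQH")) {
    colnames(z) <- paste0("L", seq_len(nv))
    out$L <- z
  }
  if (spec$classes %in% c("LQ", "LQH")) {
    q <- z^2
    colnames(q) <- paste0("Q", seq_len(nv))
    out$Q <- q
  }
  if (spec$classes %in% c("H", "LQH")) {
    hs <- lapply(seq_len(nv), function(v) {
      h <- sapply(spec$knots[, v], function(k) pmax(0, z[, v] - k))
      if (is.null(dim(h))) h <- matrix(h, nrow = nrow(z))
      colnames(h) <- paste0("H", v, "_", seq_len(spec$hinge_knots))
      h
    })
    out$H <- do.call(cbind, hs)
  }
  do.call(cbind, out)
}

#' Fit the penalized presence-background model
#'
#' Fits a log-linear Gibbs model `p(x) proportional to exp(eta(x))` over
#' the background by minimizing the penalized negative log-likelihood of
#' the presences,
#' `f(beta) = -mean_p eta + log mean_b exp(eta) + sum_f m * lambda_f * |beta_f|`,
#' with per-feature penalty `lambda_f = sd_f(background) / sqrt(n_pres)`
#' and regularization multiplier `m`. The objective is convex; it is
#' minimized by proximal gradient descent (soft-thresholding) with
#' backtracking line search, so coefficients shrink to exactly zero as
#' the multiplier grows. The fitted normalizing offset
#' `r = log mean_b exp(eta)` is stored for the cloglog transform.
#'
#' @param pres_feat,bg_feat Feature matrices for presence and background
#'   rows ([build_features()], same spec).
#' @param spec The [feature_spec()] used to build the features.
#' @param m Regularization multiplier (the tuning grid is 1..5).
#' @param max_iter,tol Optimizer controls (defaults 500 and 1e-6 on the
#'   objective change).
#' @return Object of class `pb_model`: `beta`, `n_nonzero`, `offset`,
#'   `spec`, `m`, `converged`, `objective`.
#' @export
fit_pb_model <- function(pres_feat, bg_feat, spec, m = 1,
                         max_iter = 500, tol = 1e-6) {
  Xp <- as.matrix(pres_feat); Xb <- as.matrix(bg_feat)
  np <- nrow(Xp); nb <- nrow(Xb)
  if (np < 1) stop("need at least one presence")
  if (nb < np) stop("need at least as many background rows as presences")
  lam <- m * apply(Xb, 2, sd) / sqrt(np)
  lam[lam < 1e-12] <- 1e-12
  gp <- colMeans(Xp)
  beta <- rep(0, ncol(Xb))
  obj <- function(b) {
    eta <- drop(Xb %*% b)
    mx <- max(eta)
    -sum(gp * b) + mx + log(mean(exp(eta - mx))) + sum(lam * abs(b))
  }
  smooth_grad <- function(b) {
    eta <- drop(Xb %*% b)
    w <- exp(eta - max(eta)); w <- w / sum(w)
    drop(crossprod(Xb, w)) - gp
  }
  f_old <- obj(beta)
  step <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- smooth_grad(beta)
    repeat {
      cand <- sign(beta - step * g) * pmax(0, abs(beta - step * g) - step * lam)
      f_new <- obj(cand)
      if (f_new <= f_old + 1e-12 || step < 1e-10) break
      step <- step / 2
    }
    if (step < 1e-10) break
    delta <- f_old - f_new
    beta <- cand
    f_old <- f_new
    step <- step * 1.3  # cautious step recovery
    if (delta >= 0 && delta < tol) { converged <- TRUE; break }
  }
  eta_b <- drop(Xb %*% beta)
  mx <- max(eta_b)
  structure(list(beta = beta, n_nonzero = sum(beta != 0),
                 offset = mx + log(mean(exp(eta_b - mx))),
                 spec = spec, m = m, converged = converged,
                 objective = f_old),
            class = "pb_model")
}

#' Cloglog suitability prediction
#'
#' Maps the model's linear predictor to a (0, 1) suitability scale with
#' `1 - exp(-exp(eta - r))`, where `r` is the log-mean of `exp(eta)`
#' over the training background (an entropy-equivalent normalizer fitted
#' with the model). The transform is strictly increasing in `eta`; a
#' null model (all coefficients zero) predicts the same value
#' everywhere.
#'
#' @param model A [fit_pb_model()].
#' @param values Raw environment matrix (rows to predict).
#' @return Suitability vector in (0, 1).
#' @export
predict_cloglog <- function(model, values) {
  stopifnot(inherits(model, "pb_model"))
  X <- build_features(values, model$spec)
  eta <- drop(X %*% model$beta)
  1 - exp(-exp(eta - model$offset))
}

#' Assign cross-validation folds for presences
#'
#' Species with fewer than 25 localities get leave-one-out folds (the
#' delete-one jackknife maximizes validation sample size at low n);
#' all others get a random k = 5 partition with fold sizes within one of
#' each other.
#'
#' @param n_presences Number of presence localities (>= 5; smaller
#'   species never reach the model branch).
#' @param seed Integer seed.
#' @return Object of class `fold_scheme`: `kind` (`"loo"` or
#'   `"random_k"`), `k`, `assignment` (fold index per presence).
#' @export
partition_folds <- function(n_presences, seed = 1) {
  if (n_presences < 5) stop("model branch requires >= 5 presences")
  if (n_presences < 25) {
    return(structure(list(kind = "loo", k = n_presences,
                          assignment = seq_len(n_presences)),
                     class = "fold_scheme"))
  }
  set.seed(seed)
  assignment <- sample(rep_len(1:5, n_presences))
  structure(list(kind = "random_k", k = 5, assignment = assignment),
            class = "fold_scheme")
}

# Mann-Whitney AUC of positives vs negatives (average ranks for ties)
rank_auc <- function(pos, neg) {
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Continuous Boyce Index
#'
#' Spearman correlation between the predicted-to-expected occurrence
#' ratio and window midpoint over moving suitability windows (101
#' windows of width one tenth of the background suitability range).
#' Positive values indicate predictions consistent with the occurrence
#' distribution; NA when the windows are degenerate.
#'
#' @param pres_suit,bg_suit Suitability vectors at presences and
#'   background.
#' @param n_windows,width_frac Window controls.
#' @return CBI in [-1, 1], or NA.
#' @export
continuous_boyce <- function(pres_suit, bg_suit, n_windows = 101,
                             width_frac = 0.1) {
  rng <- range(bg_suit)
  w <- diff(rng) * width_frac
  if (!is.finite(w) || w <= 0) return(NA_real_)
  mids <- seq(rng[1] + w / 2, rng[2] - w / 2, length.out = n_windows)
  pe <- vapply(mids, function(m) {
    p <- mean(pres_suit >= m - w / 2 & pres_suit <= m + w / 2)
    e <- mean(bg_suit >= m - w / 2 & bg_suit <= m + w / 2)
    if (e == 0) NA_real_ else p / e
  }, 0)
  ok <- !is.na(pe)
  if (sum(ok) < 3 || sd(pe[ok]) == 0) return(NA_real_)
  suppressWarnings(cor(pe[ok], mids[ok], method = "spearman"))
}

#' Cross-validated evaluation of one candidate setting
#'
#' Refits the model on each training fold and scores the withheld
#' presences: `or10` is the mean fraction of withheld presences whose
#' suitability falls below the 10th percentile of training-presence
#' suitability; `auc_val` the mean Mann-Whitney statistic of withheld
#' presences against the background; `cbi` the Continuous Boyce Index of
#' the full-data fit (computed on all presences, as a standard measure
#' across species). Folds without withheld presences contribute NA and
#' are skipped in the averages.
#'
#' @param pres_env,bg_env Raw environment matrices.
#' @param classes,m Candidate feature classes and multiplier.
#' @param folds A [partition_folds()] scheme.
#' @param hinge_knots Hinge knots per variable.
#' @param full_model Optional pre-fitted full-data model to reuse.
#' @return List: `metrics` (or10, auc_val, cbi, n_nonzero), `model` (the
#'   full-data fit).
#' @export
evaluate_candidate <- function(pres_env, bg_env, classes, m, folds,
                               hinge_knots = 8, full_model = NULL) {
  spec <- feature_spec(bg_env, classes = classes, hinge_knots = hinge_knots)
  Xb <- build_features(bg_env, spec)
  Xp <- build_features(pres_env, spec)
  if (is.null(full_model))
    full_model <- fit_pb_model(Xp, Xb, spec, m = m)
  or10 <- auc <- rep(NA_real_, max(folds$assignment))
  for (f in sort(unique(folds$assignment))) {
    hold <- folds$assignment == f
    if (!any(hold) || all(hold)) next
    fit <- fit_pb_model(Xp[!hold, , drop = FALSE], Xb, spec, m = m)
    train_suit <- 1 - exp(-exp(drop(Xp[!hold, , drop = FALSE] %*% fit$beta) -
                                 fit$offset))
    test_suit <- 1 - exp(-exp(drop(Xp[hold, , drop = FALSE] %*% fit$beta) -
                                fit$offset))
    bg_suit <- 1 - exp(-exp(drop(Xb %*% fit$beta) - fit$offset))
    thr <- quantile(train_suit, 0.10, names = FALSE)
    or10[f] <- mean(test_suit < thr)
    auc[f] <- rank_auc(test_suit, bg_suit)
  }
  full_pres <- 1 - exp(-exp(drop(Xp %*% full_model$beta) - full_model$offset))
  full_bg <- 1 - exp(-exp(drop(Xb %*% full_model$beta) - full_model$offset))
  cbi <- if (full_model$n_nonzero == 0) NA_real_
         else continuous_boyce(full_pres, full_bg)
  list(metrics = list(or10 = mean(or10, na.rm = TRUE),
                      auc_val = mean(auc, na.rm = TRUE),
                      cbi = cbi, n_nonzero = full_model$n_nonzero),
       model = full_model)
}

#' Sequential model selection over a candidate table
#'
#' Applies the selection filters to a table of candidate metrics:
#' (1) drop candidates with no nonzero coefficients; (2) drop candidates
#' whose CBI is NA or <= 0; (3) keep the minimum 10-percentile omission
#' rate; (4) break ties by maximum validation AUC; (5) then by minimum
#' number of nonzero coefficients; (6) residual ties go to the simpler
#' feature class (L < LQ < H < LQH) and then the smaller multiplier, so
#' selection never depends on candidate order.
#'
#' @param cand Data frame with columns `classes`, `m`, `or10`,
#'   `auc_val`, `cbi`, `n_nonzero`.
#' @return The selected row index, or NA if no candidate survives
#'   filters (1)-(2).
#' @export
select_from_candidates <- function(cand) {
  ok <- cand$n_nonzero > 0 & !is.na(cand$cbi) & cand$cbi > 0
  if (!any(ok)) return(NA_integer_)
  idx <- which(ok)
  or10 <- ifelse(is.na(cand$or10[idx]), Inf, cand$or10[idx])
  idx <- idx[or10 == min(or10)]
  if (length(idx) > 1) {
    auc <- ifelse(is.na(cand$auc_val[idx]), -Inf, cand$auc_val[idx])
    idx <- idx[auc == max(auc)]
  }
  if (length(idx) > 1)
    idx <- idx[cand$n_nonzero[idx] == min(cand$n_nonzero[idx])]
  if (length(idx) > 1) {
    rank_cls <- match(cand$classes[idx], c("L", "LQ", "H", "LQH"))
    idx <- idx[order(rank_cls, cand$m[idx])]
  }
  idx[1]
}

#' Tune and select a presence-background model
#'
#' Fits every combination of feature classes and regularization
#' multipliers, evaluates each by cross-validation, and applies the
#' sequential selection of [select_from_candidates()]. Returns a
#' `polygon_fallback` sentinel when every candidate fails the
#' coefficient and CBI filters, in which case the caller should fall
#' back to the univalue range polygon.
#'
#' @param pres_env,bg_env Raw environment matrices (presence localities
#'   and background cells).
#' @param classes Candidate feature classes (default all four).
#' @param multipliers Candidate regularization multipliers (default
#'   1:5).
#' @param hinge_knots Hinge knots per variable (default 8).
#' @param seed Seed for the fold assignment.
#' @return List of class `sdm_selection`: `model` (the chosen
#'   [fit_pb_model()]), `metrics` (candidate table), `selected` (row
#'   index), `folds`; or an object of class `polygon_fallback`.
#' @export
tune_and_select <- function(pres_env, bg_env,
                            classes = c("L", "LQ", "H", "LQH"),
                            multipliers = 1:5, hinge_knots = 8, seed = 1) {
  pres_env <- as.matrix(pres_env)
  folds <- partition_folds(nrow(pres_env), seed = seed)
  grid <- expand.grid(classes = classes, m = multipliers,
                      stringsAsFactors = FALSE)
  evals <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    evals[[i]] <- evaluate_candidate(pres_env, bg_env,
                                     classes = grid$classes[i],
                                     m = grid$m[i], folds = folds,
                                     hinge_knots = hinge_knots)
  }
  cand <- cbind(grid, do.call(rbind, lapply(evals, function(e)
    as.data.frame(e$metrics))))
  sel <- select_from_candidates(cand)
  if (is.na(sel))
    return(structure(list(metrics = cand), class = "polygon_fallback"))
  structure(list(model = evals[[sel]]$model, metrics = cand,
                 selected = sel, folds = folds),
            class = "sdm_selection")
}
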