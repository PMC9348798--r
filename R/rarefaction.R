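#' Incidence frequencies within a window
#'
#' Summarizes per-species incidences over a set of grid cells: `Y_j`
#' counts the distinct cells (not raw records) in which species `j`
#' occurs, `T` is the number of grid cells in the window, `Q1`/`Q2` the
#' unique/duplicate incidence counts and `U` the total incidences.
#'
#' @param occurrence_cells Named list: species id -> integer vector of
#'   occupied cell indices (any cells, typically from resolved records).
#' @param window_cells Integer vector of the cell indices in the window.
#' @return Object of class `incidence_freq`: `T`, `Y` (named), `S_obs`,
#'   `Q1`, `Q2`, `U`, `n_occupied_cells`.
#' @export
window_incidence <- function(occurrence_cells, window_cells) {
  Y <- vapply(occurrence_cells, function(cells)
    length(unique(intersect(cells, window_cells))), 0L)
  Y <- Y[Y > 0]
  structure(list(T = length(window_cells), Y = Y,
                 S_obs = length(Y),
                 Q1 = sum(Y == 1), Q2 = sum(Y == 2),
                 U = sum(Y),
                 n_occupied_cells =
                   length(unique(unlist(lapply(occurrence_cells, intersect,
                                               window_cells))))),
            class = "incidence_freq")
}

#' Incidence-based richness estimate (Chao2, Hill q = 0)
#'
#' Bias-corrected Chao2 lower-bound estimator and incidence-based
#' sample-coverage estimate:
#' `S_hat = S_obs + ((T-1)/T) * Q1^2 / (2 Q2)` when `Q2 > 0`, and
#' `S_obs + ((T-1)/T) * Q1 (Q1 - 1) / 2` when `Q2 = 0`;
#' `C_hat = 1 - (Q1/U) * ((T-1) Q1 / ((T-1) Q1 + 2 Q2))`.
#' The correction is non-negative, so `S_hat >= S_obs` always.
#'
#' @param freq An [window_incidence()] object (or any list with `T`,
#'   `S_obs`, `Q1`, `Q2`, `U`).
#' @return List with `S_hat` and `coverage_hat` (both NA when `U = 0`).
#' @export
chao2_estimate <- function(freq) {
  T <- freq$T; Q1 <- freq$Q1; Q2 <- freq$Q2; U <- freq$U
  if (is.null(U) || U == 0) return(list(S_hat = NA_real_, coverage_hat = NA_real_))
  k <- (T - 1) / T
  S_hat <- if (Q2 > 0) freq$S_obs + k * Q1^2 / (2 * Q2)
           else freq$S_obs + k * Q1 * (Q1 - 1) / 2
  denom <- k * Q1 + 2 * Q2
  coverage_hat <- if (denom == 0) 1 else 1 - (Q1 / U) * (k * Q1 / denom)
  list(S_hat = S_hat, coverage_hat = coverage_hat)
}

#' Window reliability filter
#'
#' A window is excluded when fewer than 2 of its grid cells contain any
#' species incidence, or when every incidence is a singleton
#' (`Q1 = U`), conditions under which the estimator is unstable.
#'
#' @param freq An [window_incidence()] object.
#' @return TRUE if the window should be included.
#' @export
window_filters <- function(freq) {
  if (freq$n_occupied_cells < 2) return(FALSE)
  if (freq$U > 0 && freq$Q1 == freq$U) return(FALSE)
  TRUE
}

#' Moving-window rarefaction/extrapolation richness map
#'
#' Slides a square window over the grid (anchors spaced by `stride`),
#' summarizes the occurrence incidences in each window, estimates
#' richness with [chao2_estimate()] where [window_filters()] passes, and
#' writes each estimate to the window's footprint; cells covered by
#' several windows receive the average of their estimates.
#'
#' @param occurrence_cells Named list: species -> occupied cell indices.
#' @param grid A [grid_spec()].
#' @param window_cells Window side length in cells (default 60).
#' @param stride Anchor spacing in cells (default `window_cells / 2`).
#' @return List: `raster` (a [div_raster()] of estimated richness, NA
#'   where no reliable window covers a cell or off land) and `windows`
#'   (per-window data frame: anchor, T, S_obs, Q1, Q2, U, S_hat,
#'   coverage, included).
#' @export
moving_window_map <- function(occurrence_cells, grid, window_cells = 60,
                              stride = max(1, window_cells %/% 2)) {
  if (window_cells < 2) stop("window_cells must be >= 2")
  acc <- matrix(0, grid$n_rows, grid$n_cols)
  cnt <- matrix(0L, grid$n_rows, grid$n_cols)
  rows0 <- unique(c(seq(1, max(1, grid$n_rows - window_cells + 1), by = stride),
                    max(1, grid$n_rows - window_cells + 1)))
  cols0 <- unique(c(seq(1, max(1, grid$n_cols - window_cells + 1), by = stride),
                    max(1, grid$n_cols - window_cells + 1)))
  win_log <- list()
  for (r0 in rows0) {
    for (c0 in cols0) {
      rr <- r0:min(grid$n_rows, r0 + window_cells - 1)
      cc <- c0:min(grid$n_cols, c0 + window_cells - 1)
      wcells <- as.vector(outer(rr, (cc - 1L) * grid$n_rows, "+"))
      freq <- window_incidence(occurrence_cells, wcells)
      inc <- window_filters(freq)
      est <- if (inc) chao2_estimate(freq)
             else list(S_hat = NA_real_, coverage_hat = NA_real_)
      win_log[[length(win_log) + 1]] <-
        data.frame(row0 = r0, col0 = c0, T = freq$T, S_obs = freq$S_obs,
                   Q1 = freq$Q1, Q2 = freq$Q2, U = freq$U,
                   S_hat = est$S_hat, coverage = est$coverage_hat,
                   included = inc)
      if (inc && !is.na(est$S_hat)) {
        acc[wcells] <- acc[wcells] + est$S_hat
        cnt[wcells] <- cnt[wcells] + 1L
      }
    }
  }
  v <- ifelse(cnt > 0, acc / cnt, NA_real_)
  v[!grid$land_mask] <- NA
  list(raster = div_raster(grid, v, "richness_rarefied"),
       windows = do.call(rbind, win_log))
}
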