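# Shared fixtures, built once per test run. The test world is a coarse
# (2-degree) variant of the default study conditions so the full chain
# stays fast while keeping latitude-dependent cell areas and all noise
# processes.

test_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- synthetic_world(seed = 20260929, resolution_arcmin = 120,
                                n_species = 60, effort = 2)
    cache
  }
})

test_qc <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      w <- test_world()
      cache <<- qc_pipeline(w$records, w$gazetteer)
    }
    cache
  }
})

# an all-land grid with ~10^4 cells for correlation calibration tests
flat_grid <- function() grid_spec(60, lon_min = 0, lon_max = 100,
                                  lat_min = -50, lat_max = 50)

# environment matrices for quick SDM fixtures: presences cluster at high
# values of a single informative gradient
sdm_fixture <- function(n_pres = 60, n_bg = 2000, seed = 9) {
  set.seed(seed)
  bg <- matrix(runif(n_bg, -2, 2), ncol = 1, dimnames = list(NULL, "env_1"))
  pres <- matrix(runif(n_pres, 0.5, 2), ncol = 1,
                 dimnames = list(NULL, "env_1"))
  list(pres = pres, bg = bg)
}
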