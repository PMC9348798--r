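make_rec <- function(n = 1, ...) {
  base <- data.frame(
    record_id = seq_len(n), species_id = "sp_0001",
    locality_text = "somewhere", country_label = "Country_01",
    admin1_label = "Country_01:adm1",
    orig_lon = 10, orig_lat = 10, geo_lon = 10, geo_lat = 10,
    precision_radius_km = 5,
    stringsAsFactors = FALSE)
  mod <- list(...)
  for (nm in names(mod)) base[[nm]] <- mod[[nm]]
  base
}

test_that("duplicate pooling keys on text, country and 4-decimal coordinates", {
  r <- make_rec(2, orig_lon = c(10.00001, 10.00002),
                orig_lat = c(5.00001, 5.00002))
  expect_equal(attr(pool_duplicates(r), "n_groups"), 1L)
  # missing coordinates group on the text key
  r2 <- make_rec(2, orig_lon = NA_real_, orig_lat = NA_real_)
  expect_equal(attr(pool_duplicates(r2), "n_groups"), 1L)
  # a 4th-decimal difference separates groups
  r3 <- make_rec(2, orig_lon = c(10.0001, 10.0002))
  expect_equal(attr(pool_duplicates(r3), "n_groups"), 2L)
  # 10 records with 3 planted duplicate pairs -> 7 groups
  r10 <- make_rec(10, locality_text = paste0("loc", c(1:7, 1:3)),
                  orig_lon = c(1:7, 1:3), orig_lat = 0)
  expect_equal(attr(pool_duplicates(r10), "n_groups"), 7L)
})

test_that("coordinate validation flags range, zero-zero and country errors", {
  w <- test_world()
  gaz <- w$gazetteer
  r <- make_rec(1, orig_lon = 191.2, orig_lat = 10)
  v <- validate_coordinates(r, gaz)
  expect_true(v$orig_out_of_range)
  v0 <- validate_coordinates(make_rec(1, orig_lon = 0, orig_lat = 0), gaz)
  expect_true(v0$orig_zero_zero)
  # a clean synthetic record carries no flags
  clean <- simulate_collection(w$pool[1:3], w$bias, 3,
                               noise_config(0, 0, 0, 0, 0), gaz, seed = 4)[1, ]
  vc <- validate_coordinates(clean, gaz)
  expect_false(vc$orig_out_of_range || vc$orig_zero_zero ||
                 vc$orig_country_mismatch || vc$orig_missing)
  # planted wrong-country labels are recovered exactly
  noisy <- simulate_collection(w$pool, w$bias, 2,
                               noise_config(0, 0.2, 0, 0, 0), gaz, seed = 5)
  vn <- validate_coordinates(noisy, gaz)
  expect_equal(vn$orig_country_mismatch, vn$truth_wrong_country)
})

test_that("resolution decision tree prioritizes originals and applies the 100-km rule", {
  w <- test_world()
  e <- w$gazetteer$entries[1, ]  # a real land locality with its country
  # valid original + valid geocode -> the original wins
  both <- validate_coordinates(
    make_rec(1, orig_lon = e$lon, orig_lat = e$lat,
             geo_lon = e$lon + 0.01, geo_lat = e$lat,
             country_label = e$country), w$gazetteer)
  res <- resolve_coordinates(both)
  expect_equal(res$provenance_class, "metadata_derived")
  expect_equal(res$resolved_lon, e$lon)
  # no original, precise geocode with agreeing country -> geocoded
  geo <- make_rec(1, orig_lon = NA_real_, orig_lat = NA_real_,
                  geo_lon = e$lon, geo_lat = e$lat,
                  precision_radius_km = 40, country_label = e$country)
  res2 <- resolve_coordinates(validate_coordinates(geo, w$gazetteer))
  expect_equal(res2$provenance_class, "geocoded")
  expect_equal(res2$resolved_lon, e$lon)
  # no original, geocode precision 150 km -> unresolved
  res3 <- resolve_coordinates(validate_coordinates(
    make_rec(1, orig_lon = NA_real_, orig_lat = NA_real_,
             geo_lon = e$lon, geo_lat = e$lat,
             precision_radius_km = 150, country_label = e$country),
    w$gazetteer))
  expect_equal(res3$provenance_class, "unresolved")
  expect_true(is.na(res3$resolved_lon))
})

test_that("centroid flagging requires both proximity and an admin-only locality", {
  w <- test_world()
  cent <- w$gazetteer$centroids
  ctry <- cent[cent$level == "country", ][1, ]
  at_centroid <- make_rec(2, locality_text = c(ctry$unit, "some village"),
                          orig_lon = ctry$lon, orig_lat = ctry$lat,
                          country_label = ctry$unit)
  r <- flag_centroids(resolve_coordinates(
    validate_coordinates(at_centroid, w$gazetteer)), w$gazetteer, tol_km = 1)
  expect_equal(r$centroid_flag, c(TRUE, FALSE))
  # planted centroid records among clean ones are recovered exactly
  noisy <- simulate_collection(w$pool, w$bias, 2,
                               noise_config(0, 0, 0, 0, 0.05),
                               w$gazetteer, seed = 6)
  out <- qc_pipeline(noisy, w$gazetteer)$records
  expect_equal(out$centroid_flag, out$truth_centroid)
})

test_that("qc reports count classes additively", {
  empty <- qc_summary(empty_record_table())
  expect_equal(empty$n_total_retained, 0)
  rep_counts <- qc_report(n_metadata_derived = 988331, n_geocoded = 490962)
  expect_identical(rep_counts$n_total_retained, 1479293)
  # counts match planted class labels on the shared noisy world
  qc <- test_qc()
  r <- qc$records
  expect_equal(qc$report$n_total_retained,
               qc$report$n_metadata_derived + qc$report$n_geocoded)
  expect_equal(qc$report$n_total_retained, nrow(qc$retained))
  expect_equal(qc$report$n_input, nrow(test_world()$records))
})

test_that("zero-noise records all resolve as metadata-derived with no flags", {
  w <- test_world()
  rec <- simulate_collection(w$pool, w$bias, 1.5, noise_config(0, 0, 0, 0, 0),
                             w$gazetteer, seed = 11)
  qc <- qc_pipeline(rec, w$gazetteer)
  expect_true(all(qc$records$provenance_class == "metadata_derived"))
  expect_equal(qc$report$n_unresolved, 0L)
  expect_false(any(qc$records$centroid_flag))
})

test_that("qc flags score >= 0.95 precision and recall against ground truth", {
  qc <- test_qc()
  r <- qc$records
  score <- function(flag, truth) {
    c(sum(flag & truth) / max(1, sum(flag)),
      sum(flag & truth) / max(1, sum(truth)))
  }
  for (pair in list(list(r$orig_country_mismatch, r$truth_wrong_country),
                    list(r$centroid_flag, r$truth_centroid),
                    list(r$orig_missing, r$truth_missing))) {
    s <- score(pair[[1]], pair[[2]])
    expect_gte(s[1], 0.95)
    expect_gte(s[2], 0.95)
  }
})

test_that("no record gains a coordinate it did not carry", {
  qc <- test_qc()
  r <- qc$retained
  from_orig <- r$provenance_class == "metadata_derived"
  expect_equal(r$resolved_lon[from_orig], r$orig_lon[from_orig])
  expect_equal(r$resolved_lon[!from_orig], r$geo_lon[!from_orig])
})
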