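#' Pool duplicate localities
#'
#' Records sharing the same normalized locality string, country label
#' and coordinates rounded to four decimal places (~11 m) are assigned
#' one locality group key, so each unique locality is geocoded (and
#' later counted) once. Records without coordinates group on the text
#' key alone.
#'
#' @param records Occurrence data frame (see [simulate_collection()] for
#'   the column contract; only `locality_text`, `country_label`,
#'   `orig_lon`, `orig_lat` are used here).
#' @return The records with a `locality_group` character column; the
#'   number of distinct groups is in attribute `n_groups`.
#' @export
pool_duplicates <- function(records) {
  norm <- function(x) tolower(trimws(x))
  coord_key <- function(x) ifelse(is.na(x), "", sprintf("%.4f", round(x, 4)))
  key <- paste(norm(records$locality_text), norm(records$country_label),
               coord_key(records$orig_lon), coord_key(records$orig_lat),
               sep = "|")
  records$locality_group <- key
  attr(records, "n_groups") <- length(unique(key))
  records
}

#' Validate candidate coordinates
#'
#' Flags (never rejects) problems with the original and geocoded
#' coordinate candidates of each record: coordinates outside +-180
#' longitude / +-90 latitude, exact (0, 0) points, missing or
#' non-numeric coordinates, and disagreement between the coordinate's
#' country (looked up in the gazetteer) and the record's country label.
#'
#' @param records Occurrence data frame.
#' @param gazetteer A [make_gazetteer()] object for country lookups.
#' @return The records with logical flag columns `orig_missing`,
#'   `orig_out_of_range`, `orig_zero_zero`, `orig_country_mismatch`,
#'   `geo_missing`, `geo_country_mismatch`.
#' @export
validate_coordinates <- function(records, gazetteer) {
  norm <- function(x) tolower(trimws(x))
  olon <- suppressWarnings(as.numeric(records$orig_lon))
  olat <- suppressWarnings(as.numeric(records$orig_lat))
  records$orig_missing <- is.na(olon) | is.na(olat)
  records$orig_out_of_range <- !records$orig_missing &
    (abs(olon) > 180 | abs(olat) > 90)
  records$orig_zero_zero <- !records$orig_missing & olon == 0 & olat == 0
  usable <- !records$orig_missing & !records$orig_out_of_range
  oc <- rep(NA_character_, nrow(records))
  if (any(usable)) oc[usable] <- lookup_country(gazetteer, olon[usable], olat[usable])
  records$orig_country_mismatch <- usable &
    (is.na(oc) | norm(oc) != norm(records$country_label))
  glon <- suppressWarnings(as.numeric(records$geo_lon))
  glat <- suppressWarnings(as.numeric(records$geo_lat))
  records$geo_missing <- is.na(glon) | is.na(glat)
  gusable <- !records$geo_missing & abs(glon) <= 180 & abs(glat) <= 90
  gc <- rep(NA_character_, nrow(records))
  if (any(gusable)) gc[gusable] <- lookup_country(gazetteer, glon[gusable], glat[gusable])
  records$geo_country_mismatch <- !records$geo_missing &
    (!gusable | is.na(gc) | norm(gc) != norm(records$country_label))
  records
}

#' Resolve record coordinates by the selection decision tree
#'
#' Chooses one coordinate per record from the validated candidates,
#' prioritizing coordinates carried by the original record metadata:
#' (1) an original coordinate with no out-of-range, zero-zero or
#' country-mismatch flag is used (`provenance_class = "metadata_derived"`);
#' (2) otherwise a geocoded coordinate with no country mismatch and a
#' precision radius of at most `max_precision_km` is used
#' (`"geocoded"`); (3) otherwise the record stays `"unresolved"` and is
#' excluded from analysis. A missing precision radius on the geocoded
#' branch is treated as unusable; a record never gains a coordinate it
#' did not carry as a candidate.
#'
#' @param records Output of [validate_coordinates()].
#' @param max_precision_km Geocode usability cutoff (default 100 km).
#' @return The records with `resolved_lon`, `resolved_lat`,
#'   `provenance_class` columns.
#' @export
resolve_coordinates <- function(records, max_precision_km = 100) {
  need <- c("orig_missing", "orig_out_of_range", "orig_zero_zero",
            "orig_country_mismatch", "geo_missing", "geo_country_mismatch")
  if (!all(need %in% names(records)))
    stop("run validate_coordinates() first")
  use_orig <- !records$orig_missing & !records$orig_out_of_range &
    !records$orig_zero_zero & !records$orig_country_mismatch
  prec_ok <- !is.na(records$precision_radius_km) &
    records$precision_radius_km <= max_precision_km
  use_geo <- !use_orig & !records$geo_missing &
    !records$geo_country_mismatch & prec_ok
  records$resolved_lon <- ifelse(use_orig, records$orig_lon,
                                 ifelse(use_geo, records$geo_lon, NA_real_))
  records$resolved_lat <- ifelse(use_orig, records$orig_lat,
                                 ifelse(use_geo, records$geo_lat, NA_real_))
  records$provenance_class <- ifelse(use_orig, "metadata_derived",
                                     ifelse(use_geo, "geocoded", "unresolved"))
  records
}

#' Flag records georeferenced to admin-unit centroids
#'
#' A record is flagged when its resolved coordinate lies within `tol_km`
#' of a country or admin-1 centroid *and* its locality string names that
#' unit (rather than a finer place); such records carry no information
#' beyond the admin unit and are excluded from analysis.
#'
#' @param records Output of [resolve_coordinates()].
#' @param gazetteer A [make_gazetteer()] object (provides centroids).
#' @param tol_km Distance tolerance in km (default 1; centroids are
#'   exact in the synthetic gazetteer).
#' @return The records with a logical `centroid_flag` column.
#' @export
flag_centroids <- function(records, gazetteer, tol_km = 1) {
  if (!"provenance_class" %in% names(records))
    stop("run resolve_coordinates() first")
  cent <- gazetteer$centroids
  norm <- function(x) tolower(trimws(x))
  flag <- rep(FALSE, nrow(records))
  cand <- which(records$provenance_class != "unresolved" &
                  norm(records$locality_text) %in% norm(cent$unit))
  if (length(cand)) {
    m <- match(norm(records$locality_text[cand]), norm(cent$unit))
    d <- geosphere::distHaversine(
      cbind(records$resolved_lon[cand], records$resolved_lat[cand]),
      cbind(cent$lon[m], cent$lat[m])) / 1000
    flag[cand] <- d <= tol_km
  }
  records$centroid_flag <- flag
  records
}

#' Summarize quality control as a report
#'
#' Counts records per provenance class after resolution and centroid
#' flagging. Retained records are the resolved, non-centroid ones, so
#' `n_total_retained` is always the sum of the metadata-derived and
#' geocoded counts.
#'
#' @param records Output of the QC chain ([resolve_coordinates()],
#'   optionally [flag_centroids()]).
#' @return A `qc_report` object (see [qc_report()]).
#' @export
qc_summary <- function(records) {
  if (nrow(records) == 0)
    return(qc_report(0, 0, n_input = 0, n_pooled_localities = 0,
                     n_unresolved = 0))
  cflag <- if ("centroid_flag" %in% names(records)) records$centroid_flag
           else rep(FALSE, nrow(records))
  keep <- records$provenance_class != "unresolved" & !cflag
  flags <- intersect(c("orig_out_of_range", "orig_zero_zero",
                       "orig_country_mismatch", "orig_missing",
                       "geo_country_mismatch", "centroid_flag"),
                     names(records))
  n_flagged <- vapply(flags, function(f) sum(records[[f]]), 0L)
  n_groups <- if (!is.null(attr(records, "n_groups"))) attr(records, "n_groups")
              else if ("locality_group" %in% names(records))
                length(unique(records$locality_group))
              else NA_integer_
  qc_report(
    n_metadata_derived = sum(keep & records$provenance_class == "metadata_derived"),
    n_geocoded = sum(keep & records$provenance_class == "geocoded"),
    n_input = nrow(records),
    n_pooled_localities = n_groups,
    n_unresolved = sum(records$provenance_class == "unresolved"),
    n_flagged_by_flag = as.list(n_flagged))
}

#' Construct a QC report
#'
#' @param n_metadata_derived,n_geocoded Retained record counts by
#'   provenance class; their sum defines `n_total_retained`.
#' @param n_input,n_pooled_localities,n_unresolved Optional bookkeeping
#'   counts.
#' @param n_flagged_by_flag Named list of per-flag counts.
#' @return Object of class `qc_report`.
#' @export
qc_report <- function(n_metadata_derived, n_geocoded, n_input = NA_integer_,
                      n_pooled_localities = NA_integer_,
                      n_unresolved = NA_integer_,
                      n_flagged_by_flag = list()) {
  stopifnot(n_metadata_derived >= 0, n_geocoded >= 0)
  structure(list(n_input = n_input,
                 n_pooled_localities = n_pooled_localities,
                 n_metadata_derived = n_metadata_derived,
                 n_geocoded = n_geocoded,
                 n_unresolved = n_unresolved,
                 n_total_retained = n_metadata_derived + n_geocoded,
                 n_flagged_by_flag = n_flagged_by_flag),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  input records:      %s\n", format(x$n_input, big.mark = ",")))
  cat(sprintf("  pooled localities:  %s\n",
              format(x$n_pooled_localities, big.mark = ",")))
  cat(sprintf("  metadata-derived:   %s\n",
              format(x$n_metadata_derived, big.mark = ",")))
  cat(sprintf("  geocoded:           %s\n", format(x$n_geocoded, big.mark = ",")))
  cat(sprintf("  unresolved:         %s\n", format(x$n_unresolved, big.mark = ",")))
  cat(sprintf("  total retained:     %s\n",
              format(x$n_total_retained, big.mark = ",")))
  invisible(x)
}

#' Run the full occurrence QC chain
#'
#' Pools duplicate localities, validates candidate coordinates, resolves
#' one coordinate per record by the decision tree, flags admin-centroid
#' records, and returns the cleaned table plus a report. The analysis
#' set is the retained rows (`resolved & !centroid_flag`).
#'
#' @param records Raw occurrence data frame.
#' @param gazetteer A [make_gazetteer()] object.
#' @param max_precision_km Geocode usability cutoff (default 100 km).
#' @param centroid_tol_km Centroid distance tolerance (default 1 km).
#' @return List with `records` (all rows, annotated), `retained`
#'   (analysis rows) and `report` (a [qc_report()]).
#' @export
qc_pipeline <- function(records, gazetteer, max_precision_km = 100,
                        centroid_tol_km = 1) {
  r <- pool_duplicates(records)
  r <- validate_coordinates(r, gazetteer)
  r <- resolve_coordinates(r, max_precision_km = max_precision_km)
  r <- flag_centroids(r, gazetteer, tol_km = centroid_tol_km)
  keep <- r$provenance_class != "unresolved" & !r$centroid_flag
  list(records = r, retained = r[keep, , drop = FALSE], report = qc_summary(r))
}
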