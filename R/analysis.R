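#' Occurrence records
#'
#' Presence-only longitude/latitude points with a country label and a
#' source tag (`literature`, `GBIF` or `synthetic`).
#'
#' @param lon,lat Coordinates, degrees east / north.
#' @param country Country labels (recycled).
#' @param source Source tags (recycled).
#' @return A data frame of class `occurrence_records`.
#' @export
occurrence_records <- function(lon, lat, country = "", source = "synthetic") {
  lon <- as.numeric(lon); lat <- as.numeric(lat)
  if (length(lon) != length(lat))
    stop_validation("lon and lat lengths differ")
  if (any(lon < -180 | lon >= 360 | lat < -90 | lat > 90, na.rm = TRUE))
    stop_validation("coordinates outside valid ranges")
  lon <- ifelse(lon >= 180, lon - 360, lon)  # normalise to [-180, 180)
  df <- data.frame(lon = lon, lat = lat,
                   country = rep_len(as.character(country), length(lon)),
                   source = rep_len(as.character(source), length(lon)),
                   stringsAsFactors = FALSE)
  class(df) <- c("occurrence_records", "data.frame")
  df
}

#' Read / write occurrence CSV
#'
#' Columns: `lon`, `lat`, `country`, `source`.
#'
#' @param path CSV path.
#' @return [read_occurrences()]: an `occurrence_records` data frame.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop_io("occurrence CSV not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lon", "lat")
  if (!all(need %in% names(df)))
    stop_validation("occurrence CSV must have lon and lat columns")
  occurrence_records(df$lon, df$lat,
                     country = df$country %||% "",
                     source = df$source %||% "unknown")
}

#' @rdname read_occurrences
#' @param records An `occurrence_records` data frame.
#' @return [write_occurrences()]: `path`, invisibly.
#' @export
write_occurrences <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' Merge occurrence sets and drop duplicate localities
#'
#' Stacks any number of record sets (e.g. literature-derived and
#' database-derived) and removes records that duplicate an earlier record's
#' coordinates (equal to within `digits` decimal places, about 11 m at
#' 4 digits). The first occurrence of a locality is kept, so source labels
#' of retained records follow the input order.
#'
#' @param ... `occurrence_records` data frames.
#' @param digits Coordinate rounding used for duplicate detection.
#' @return A de-duplicated `occurrence_records` data frame.
#' @export
merge_occurrences <- function(..., digits = 4) {
  sets <- list(...)
  if (!length(sets)) stop_validation("no record sets given")
  all <- do.call(rbind, lapply(sets, as.data.frame))
  key <- paste(round(all$lon, digits), round(all$lat, digits))
  out <- all[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("occurrence_records", "data.frame")
  out
}

# cell index lookup: cell-centre registration, half-open intervals,
# west/south edges inclusive. Returns NA for off-raster points.
.cell_index <- function(raster, lon, lat) {
  res <- raster$resolution
  j <- floor((lon - (raster$lon[1] - res / 2)) / res) + 1
  i <- floor(((raster$lat[1] + res / 2) - lat) / res) + 1
  # the north edge of the top row is the raster boundary: include it
  i[lat == raster$lat[1] + res / 2] <- 1
  off <- j < 1 | j > length(raster$lon) | i < 1 | i > length(raster$lat)
  i[off] <- NA_integer_; j[off] <- NA_integer_
  cbind(i = i, j = j)
}

#' Verify occurrence records against a suitability raster
#'
#' Annotates each record with the Ecoclimatic Index of its containing grid
#' cell (cell-centre registration, west/south cell edges inclusive) and
#' reports the fraction of on-raster records with EI > 0, the standard
#' presence-prediction check for compare-locations output. Records outside
#' the raster or in masked (sea / no-data) cells are flagged and excluded
#' from the fraction.
#'
#' @param records An `occurrence_records` data frame (must be non-empty).
#' @param raster A `suitability_raster` from [run_grid()].
#' @return A list of class `occurrence_verification`: `records` (with
#'   `ei` and `status` columns: `predicted`, `missed`, `masked`,
#'   `off_raster`), `fraction_predicted`, `n_evaluated`, `n_excluded`.
#' @export
verify_occurrences <- function(records, raster) {
  if (NROW(records) == 0L) stop_validation("no records")
  df <- as.data.frame(records)
  ij <- .cell_index(raster, df$lon, df$lat)
  ei <- rep(NA_real_, nrow(df))
  on <- !is.na(ij[, 1])
  ei[on] <- raster$ei[ij[on, , drop = FALSE]]
  status <- ifelse(!on, "off_raster",
            ifelse(is.na(ei), "masked",
            ifelse(ei > 0, "predicted", "missed")))
  df$ei <- ei
  df$status <- status
  evaluated <- status %in% c("predicted", "missed")
  n_excl <- sum(!evaluated)
  if (n_excl > 0)
    message(n_excl, " record(s) off-raster or in masked cells; excluded")
  structure(list(records = df,
                 fraction_predicted = if (any(evaluated))
                   mean(status[evaluated] == "predicted") else NA_real_,
                 n_evaluated = sum(evaluated), n_excluded = n_excl),
            class = "occurrence_verification")
}

#' @export
print.occurrence_verification <- function(x, ...) {
  cat(sprintf("Occurrence verification: %d evaluated, %d excluded\n",
              x$n_evaluated, x$n_excluded))
  cat(sprintf("  fraction with EI > 0 (correctly predicted presence): %.3f\n",
              x$fraction_predicted))
  invisible(x)
}

# exact spherical band area of a res x res cell centred at latitude lat
# (degrees): A = R^2 * dlon_rad * (sin(lat_n) - sin(lat_s)), in km^2
.cell_area_km2 <- function(lat, res, radius_km = 6371) {
  lat_n <- pmin(lat + res / 2, 90) * pi / 180
  lat_s <- pmax(lat - res / 2, -90) * pi / 180
  radius_km^2 * (res * pi / 180) * (sin(lat_n) - sin(lat_s))
}

#' Regional suitable-area summary
#'
#' Sums land area and climatically suitable area (EI at or above a cutoff,
#' default 1) per region, plus a world row. Cell areas are exact spherical
#' band areas, so high-latitude cells weigh less (area proportional to the
#' cosine of latitude).
#'
#' @param raster A `suitability_raster` with per-cell `region` labels (the
#'   region matrix of the input grid; unlabelled land cells are grouped
#'   under `"unlabeled"`).
#' @param threshold Suitability cutoff on EI (default 1).
#' @param world_label Name of the all-regions row (default `"World"`).
#' @return A data frame of class `regional_summary` with columns `region`,
#'   `total_area_mkm2`, `suitable_area_mkm2`, `pct_suitable`.
#' @export
regional_area_summary <- function(raster, threshold = 1,
                                  world_label = "World") {
  if (threshold < 0) stop_validation("threshold must be >= 0")
  idx <- which(raster$mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop_validation("raster has no land cells")
  area <- .cell_area_km2(raster$lat[idx[, 1]], raster$resolution)
  ei <- raster$ei[idx]
  region <- if (!is.null(raster$region)) raster$region[idx]
            else rep(NA_character_, nrow(idx))
  region[is.na(region) | !nzchar(region)] <- "unlabeled"
  agg <- function(keep, name) {
    a <- sum(area[keep]); s <- sum(area[keep & ei >= threshold])
    data.frame(region = name, total_area_mkm2 = a / 1e6,
               suitable_area_mkm2 = s / 1e6,
               pct_suitable = if (a > 0) 100 * s / a else NA_real_,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(sort(unique(region)), function(r) agg(region == r, r))
  out <- rbind(do.call(rbind, rows), agg(rep(TRUE, length(ei)), world_label))
  class(out) <- c("regional_summary", "data.frame")
  attr(out, "threshold") <- threshold
  out
}

#' Annual growth curve for one location
#'
#' The 52-week table behind a growth-curve figure — weekly mean
#' temperature, rainfall, temperature index and growth index — plus the
#' stressful periods of the year: maximal (cyclic) runs of weeks where the
#' growth index falls below a fraction of its annual maximum.
#'
#' @param n A [climate_normals()] object.
#' @param p A [species_parameters()] object.
#' @param h A [hydro_constants()] object.
#' @param low_frac Stressful-period cutoff as a fraction of the annual
#'   maximum weekly GI (default 0.5). Ignored when the whole year has zero
#'   growth (then every week is stressful).
#' @return A data frame of class `growth_curve` (52 rows: `week`, `tmean`,
#'   `rain`, `ti`, `mi`, `gi`, `sm`) with attributes `stress_periods` (data
#'   frame of `start`, `end`, `length` in weeks, cyclic) and `result` (the
#'   full `eco_location`).
#' @export
growth_curve <- function(n, p, h = hydro_constants(), low_frac = 0.5) {
  res <- run_location(n, p, h)
  wk <- res$weekly
  out <- wk[, c("week", "tmean", "rain", "ti", "mi", "gi", "sm")]
  cutoff <- low_frac * max(wk$gi)
  low <- if (max(wk$gi) > 0) wk$gi < cutoff else rep(TRUE, 52)
  attr(out, "stress_periods") <- .cyclic_runs(low)
  attr(out, "cutoff") <- cutoff
  attr(out, "result") <- res
  class(out) <- c("growth_curve", "data.frame")
  out
}

# maximal cyclic runs of TRUE weeks as start/end/length (1-based weeks;
# a run crossing the year boundary has start > end)
.cyclic_runs <- function(flag) {
  n <- length(flag)
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0))
  if (!any(flag)) return(empty)
  if (all(flag)) return(data.frame(start = 1L, end = n, length = n))
  runs <- stress_run_lengths(as.numeric(flag))
  nxt <- c(flag[-1], flag[1])
  ends <- which(flag & !nxt)
  data.frame(start = (ends - runs[ends]) %% n + 1L, end = ends,
             length = runs[ends])
}

#' @export
print.growth_curve <- function(x, ...) {
  res <- attr(x, "result")
  cat(sprintf("Growth curve%s: annual GI %.1f, EI %.1f\n",
              if (nzchar(res$label)) paste0(" for ", res$label) else "",
              res$gi_annual, res$ei))
  sp <- attr(x, "stress_periods")
  if (nrow(sp) == 0) {
    cat("  no stressful period (GI never falls below the cutoff)\n")
  } else {
    for (k in seq_len(nrow(sp)))
      cat(sprintf("  stressful period: weeks %d-%d (%d weeks)\n",
                  sp$start[k], sp$end[k], sp$length[k]))
  }
  invisible(x)
}

#' @export
plot.growth_curve <- function(x, ...) {
  plot(attr(x, "result"), ...)
}
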