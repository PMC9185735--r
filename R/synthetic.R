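# Synthetic Koppen-Geiger climate archetypes. The shipped defaults are
# textbook climatologies for each class — calibration fixtures for the
# test-bed, not claims about real stations.

.archetype_table <- function() {
  data.frame(
    name = c("Af", "Aw", "BWh", "Csa", "Cfb", "Dfb"),
    description = c("tropical rainforest", "tropical savanna",
                    "hot desert", "Mediterranean", "temperate oceanic",
                    "cold continental"),
    mean_temp = c(26, 26, 29, 17, 11, 6),
    seasonal_amplitude = c(1, 3, 9, 7.5, 7, 14),
    diurnal_range = c(8, 10, 16, 8, 8, 10),
    annual_rainfall = c(2000, 1200, 100, 600, 800, 700),
    rainfall_shape = c("uniform", "summer-peak", "uniform", "winter-peak",
                       "uniform", "summer-peak"),
    rh_baseline = c(82, 70, 30, 70, 78, 72),
    stringsAsFactors = FALSE)
}

#' Shipped Koppen-Geiger climate archetypes
#'
#' Returns the archetype table used by [generate_archetype_normals()]:
#' annual mean temperature (degrees C), seasonal amplitude of the monthly
#' mean (degrees C), mean diurnal range (degrees C), annual rainfall (mm),
#' rainfall seasonality shape (`uniform`, `summer-peak`, `winter-peak`)
#' and baseline relative humidity (percent) for the six codes Af, Aw,
#' BWh, Csa, Cfb and Dfb.
#'
#' @return A data frame, one row per archetype.
#' @export
koppen_archetypes <- function() .archetype_table()

#' Build or look up an archetype specification
#'
#' @param name A Koppen-Geiger code from [koppen_archetypes()].
#' @param ... Optional overrides of the archetype fields (e.g.
#'   `annual_rainfall = 3000`).
#' @return A one-row `archetype_spec` data frame.
#' @export
archetype_spec <- function(name, ...) {
  tab <- .archetype_table()
  i <- match(name, tab$name)
  if (is.na(i))
    stop_validation("unknown archetype %s; valid codes: %s", name,
                    paste(tab$name, collapse = ", "))
  spec <- tab[i, , drop = FALSE]
  over <- list(...)
  bad <- setdiff(names(over), names(spec))
  if (length(bad))
    stop_validation("unknown archetype field(s): %s", paste(bad, collapse = ", "))
  for (f in names(over)) spec[[f]] <- over[[f]]
  if (spec$seasonal_amplitude < 0 || spec$annual_rainfall < 0)
    stop_validation("amplitude and rainfall must be >= 0")
  rownames(spec) <- NULL
  class(spec) <- c("archetype_spec", "data.frame")
  spec
}

# monthly seasonal phase: +1 in the warm season. Peak in July north of the
# equator, January south of it.
.seasonal_phase <- function(lat) {
  m <- 1:12
  if (lat >= 0) cos(2 * pi * (m - 7) / 12) else cos(2 * pi * (m - 1) / 12)
}

#' Generate monthly climate normals for a Koppen archetype
#'
#' Builds a 12-month sinusoidal temperature cycle (warm-season phase set by
#' the hemisphere of `lat`), distributes the annual rainfall per the
#' seasonality shape, and sets humidity near the baseline (slightly higher
#' in the rainy season). Optional Gaussian jitter makes grid cells
#' non-identical; with `jitter_sd = 0` the output is a deterministic
#' function of the spec and latitude.
#'
#' @param spec An [archetype_spec()] or a Koppen code string.
#' @param lat Latitude, degrees north (controls the seasonal phase).
#' @param lon Longitude, degrees east (label/metadata only).
#' @param seed Integer seed used when `jitter_sd > 0`.
#' @param jitter_sd Standard deviation of the temperature jitter (degrees
#'   C); rainfall is jittered proportionally (2 percent per degree
#'   equivalent) and humidity by half of it.
#' @param label Station label (defaults to the archetype code).
#' @return A [climate_normals()] object.
#' @export
generate_archetype_normals <- function(spec, lat, lon = 0, seed = 1L,
                                       jitter_sd = 0, label = NULL) {
  if (is.character(spec)) spec <- archetype_spec(spec)
  phase <- .seasonal_phase(lat)
  tmean <- spec$mean_temp + spec$seasonal_amplitude * phase
  tmax <- tmean + spec$diurnal_range / 2
  tmin <- tmean - spec$diurnal_range / 2
  wgt <- switch(spec$rainfall_shape,
                uniform = rep(1, 12),
                `summer-peak` = pmax(0, 1 + 0.9 * phase),
                `winter-peak` = pmax(0, 1 - 0.9 * phase),
                stop_validation("unknown rainfall shape: %s",
                                spec$rainfall_shape))
  ptotal <- spec$annual_rainfall * wgt / sum(wgt)
  rainy <- if (max(wgt) > min(wgt))
    (wgt - mean(wgt)) / (max(wgt) - min(wgt)) else rep(0, 12)
  rh <- pmin(pmax(spec$rh_baseline + 6 * rainy, 2), 98)
  if (jitter_sd > 0) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
    dt <- stats::rnorm(12, 0, jitter_sd)
    tmean_j <- tmean + dt
    tmax <- tmean_j + spec$diurnal_range / 2
    tmin <- tmean_j - spec$diurnal_range / 2
    ptotal <- pmax(0, ptotal * (1 + 0.02 * stats::rnorm(12, 0, jitter_sd)))
    rh <- pmin(pmax(rh + stats::rnorm(12, 0, jitter_sd / 2), 2), 98)
  }
  climate_normals(tmax, tmin, ptotal, pmin(rh + 4, 100), pmax(rh - 4, 0),
                  lon = lon, lat = lat,
                  label = label %||% spec$name)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic climate grid from archetype blocks
#'
#' Tiles a matrix of archetype codes over a regular lon/lat lattice: each
#' layout entry becomes a block of `block` x `block` cells whose normals
#' come from the archetype at the cell's latitude, with independent seeded
#' jitter per cell. `NA` layout entries become masked (sea) cells. Region
#' labels default to the archetype code.
#'
#' @param layout A character matrix of archetype codes (rows = north to
#'   south).
#' @param block Cells per layout entry along each axis (default 1).
#' @param resolution Cell size in degrees (default 0.5).
#' @param origin `c(lon, lat)` of the north-west cell centre
#'   (default `c(0, 0)`).
#' @param seed Integer seed for the jitter.
#' @param jitter_sd Per-cell temperature jitter SD in degrees C
#'   (default 0 = exactly block-constant).
#' @param region Optional character matrix like `layout` giving region
#'   labels per block.
#' @return A [climate_grid()].
#' @export
generate_grid <- function(layout, block = 1L, resolution = 0.5,
                          origin = c(0, 0), seed = 1L, jitter_sd = 0,
                          region = NULL) {
  layout <- as.matrix(layout)
  nlat <- nrow(layout) * block
  nlon <- ncol(layout) * block
  lon <- origin[1] + (seq_len(nlon) - 1) * resolution
  lat <- origin[2] - (seq_len(nlat) - 1) * resolution
  dims <- c(nlat, nlon, 12L)
  vars <- list(tmax = array(NA_real_, dims), tmin = array(NA_real_, dims),
               ptotal = array(NA_real_, dims), rh09 = array(NA_real_, dims),
               rh15 = array(NA_real_, dims))
  reg <- matrix(NA_character_, nlat, nlon)
  for (bi in seq_len(nrow(layout))) for (bj in seq_len(ncol(layout))) {
    code <- layout[bi, bj]
    if (is.na(code)) next
    spec <- archetype_spec(code)
    for (ii in seq_len(block)) for (jj in seq_len(block)) {
      i <- (bi - 1L) * block + ii
      j <- (bj - 1L) * block + jj
      n <- generate_archetype_normals(spec, lat = lat[i], lon = lon[j],
                                      seed = seed + 7919L * i + j,
                                      jitter_sd = jitter_sd)
      vars$tmax[i, j, ] <- n$tmax; vars$tmin[i, j, ] <- n$tmin
      vars$ptotal[i, j, ] <- n$ptotal
      vars$rh09[i, j, ] <- n$rh09; vars$rh15[i, j, ] <- n$rh15
      reg[i, j] <- if (!is.null(region)) region[bi, bj] else code
    }
  }
  climate_grid(lon, lat, vars$tmax, vars$tmin, vars$ptotal, vars$rh09,
               vars$rh15, region = reg)
}

#' Sample synthetic occurrence records from a suitability raster
#'
#' Emulates presence-only occurrence data: records fall in cells with
#' EI > 0, except that each record independently has probability
#' `miss_rate` of being drawn from an unsuitable (EI = 0) cell instead —
#' the occasional record the climate model cannot explain (a favourable
#' microhabitat in an unsuitable region). Point coordinates are uniform
#' within the chosen cell. Seeded and reproducible.
#'
#' @param raster A `suitability_raster` with at least one EI > 0 cell.
#' @param n Number of records.
#' @param seed Integer seed.
#' @param miss_rate Probability a record falls in an EI = 0 cell
#'   (default 0).
#' @param source Source tag for the records.
#' @return An `occurrence_records` data frame.
#' @export
generate_occurrences <- function(raster, n, seed = 1L, miss_rate = 0,
                                 source = "synthetic") {
  idx <- which(raster$mask, arr.ind = TRUE)
  ei <- raster$ei[idx]
  good <- which(ei > 0)
  badc <- which(ei == 0)
  if (!length(good)) stop_validation("raster has no cells with EI > 0")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  n_miss <- stats::rbinom(1, n, miss_rate)
  if (n_miss > 0 && !length(badc)) {
    warning("no EI = 0 cells available; all records drawn from suitable cells")
    n_miss <- 0L
  }
  pick <- c(good[sample.int(length(good), n - n_miss, replace = TRUE)],
            if (n_miss > 0) badc[sample.int(length(badc), n_miss,
                                            replace = TRUE)])
  pick <- pick[sample.int(length(pick))]  # shuffle miss records in
  res <- raster$resolution
  cl <- idx[pick, , drop = FALSE]
  lon <- raster$lon[cl[, 2]] + stats::runif(n, -res / 2, res / 2)
  lat <- raster$lat[cl[, 1]] + stats::runif(n, -res / 2, res / 2)
  country <- if (!is.null(raster$region)) raster$region[cl] else ""
  occurrence_records(lon, pmin(pmax(lat, -90), 90),
                     country = country, source = source)
}
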