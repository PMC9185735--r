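#' Gridded climate normals on a regular lon/lat lattice
#'
#' Cell-centre registered, north-up grid of monthly normals. Each variable
#' is an array `[nlat, nlon, 12]` with row 1 the northernmost latitude.
#' Cells with any missing monthly value are masked out (no infilling).
#'
#' @param lon,lat Cell-centre coordinate vectors; `lon` increasing,
#'   `lat` decreasing (north-up), both regularly spaced with the same step.
#' @param tmax,tmin,ptotal,rh09,rh15 Arrays `[nlat, nlon, 12]`.
#' @param region Optional character matrix `[nlat, nlon]` of region labels
#'   for area summaries.
#' @return An object of class `climate_grid` with a logical `mask` matrix
#'   (`TRUE` = usable land cell) and the cell `resolution` in degrees.
#' @export
climate_grid <- function(lon, lat, tmax, tmin, ptotal, rh09, rh15,
                         region = NULL) {
  lon <- as.numeric(lon); lat <- as.numeric(lat)
  .check_regular(lon, "lon", increasing = TRUE)
  .check_regular(lat, "lat", increasing = FALSE)
  res_lon <- if (length(lon) > 1) diff(lon)[1] else NA_real_
  res_lat <- if (length(lat) > 1) -diff(lat)[1] else NA_real_
  res <- if (is.na(res_lon)) res_lat else res_lon
  if (!is.na(res_lon) && !is.na(res_lat) &&
      abs(res_lon - res_lat) > 1e-9 * max(res_lon, res_lat))
    stop_validation("lon and lat cell sizes differ (%g vs %g)", res_lon, res_lat)
  vars <- list(tmax = tmax, tmin = tmin, ptotal = ptotal,
               rh09 = rh09, rh15 = rh15)
  dims <- c(length(lat), length(lon), 12L)
  for (v in names(vars))
    if (!identical(dim(vars[[v]]), dims))
      stop_validation("variable %s has dimensions %s; expected %s", v,
                      paste(dim(vars[[v]]), collapse = "x"),
                      paste(dims, collapse = "x"))
  mask <- apply(!is.na(vars$tmax) & !is.na(vars$tmin) & !is.na(vars$ptotal) &
                  !is.na(vars$rh09) & !is.na(vars$rh15), c(1, 2), all)
  structure(c(list(lon = lon, lat = lat, resolution = res, mask = mask,
                   region = region), vars),
            class = "climate_grid")
}

.check_regular <- function(x, name, increasing = TRUE) {
  if (length(x) < 1L) stop_validation("%s axis is empty", name)
  if (length(x) == 1L) return(invisible())
  d <- diff(x)
  if (increasing && any(d <= 0)) stop_validation("%s axis must increase", name)
  if (!increasing && any(d >= 0))
    stop_validation("%s axis must decrease (north-up)", name)
  if (max(abs(d - d[1])) > 1e-8 * abs(d[1]))
    stop_validation("%s axis is not a regular lattice", name)
  invisible()
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("Climate grid: %d x %d cells at %.4g deg, %d land cells\n",
              length(x$lat), length(x$lon), x$resolution, sum(x$mask)))
  cat(sprintf("  lon %.3f..%.3f, lat %.3f..%.3f%s\n",
              min(x$lon), max(x$lon), min(x$lat), max(x$lat),
              if (!is.null(x$region)) sprintf(", %d region(s)",
                length(unique(stats::na.omit(as.vector(x$region))))) else ""))
  invisible(x)
}

#' Read gridded climate normals from wide CSV
#'
#' One row per land cell with the same 60 monthly columns as the station
#' CSV plus `lon`, `lat` and an optional `region` column; the lattice is
#' inferred from the unique cell-centre coordinates, and absent cells are
#' masked (treated as sea / no data).
#'
#' @param path CSV path as written by [write_climate_grid()].
#' @return A [climate_grid()].
#' @export
read_climate_grid <- function(path) {
  if (!file.exists(path)) stop_io("grid CSV not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- setdiff(.station_columns(), "label")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_validation("grid CSV missing column(s): %s",
                    paste(missing, collapse = ", "))
  if (nrow(df) == 0L) stop_validation("grid CSV contains no cells")
  lon <- sort(unique(df$lon))
  lat <- sort(unique(df$lat), decreasing = TRUE)
  dims <- c(length(lat), length(lon), 12L)
  arr <- function(v) {
    a <- array(NA_real_, dims)
    i <- match(df$lat, lat); j <- match(df$lon, lon)
    for (m in 1:12) a[cbind(i, j, m)] <- df[[paste0(v, "_", m)]]
    a
  }
  region <- NULL
  if ("region" %in% names(df)) {
    region <- matrix(NA_character_, dims[1], dims[2])
    region[cbind(match(df$lat, lat), match(df$lon, lon))] <- df$region
  }
  climate_grid(lon, lat, arr("tmax"), arr("tmin"), arr("ptotal"),
               arr("rh09"), arr("rh15"), region = region)
}

#' Write gridded climate normals to wide CSV
#'
#' Inverse of [read_climate_grid()]; masked cells are omitted, so the
#' round trip reproduces the land cells and mask exactly.
#'
#' @param g A [climate_grid()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_climate_grid <- function(g, path) {
  idx <- which(g$mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop_validation("grid has no unmasked cells to write")
  cols <- list(lon = g$lon[idx[, 2]], lat = g$lat[idx[, 1]])
  if (!is.null(g$region)) cols$region <- g$region[idx]
  for (v in c("tmax", "tmin", "ptotal", "rh09", "rh15"))
    for (m in 1:12)
      cols[[paste0(v, "_", m)]] <- g[[v]][cbind(idx, m)]
  utils::write.csv(as.data.frame(cols, check.names = FALSE), path,
                   row.names = FALSE)
  invisible(path)
}

#' Extract one cell of a climate grid as station normals
#'
#' @param g A [climate_grid()].
#' @param i,j Row (latitude) and column (longitude) indices.
#' @return A [climate_normals()] object.
#' @export
grid_cell_normals <- function(g, i, j) {
  if (!g$mask[i, j]) stop_validation("cell [%d, %d] is masked", i, j)
  climate_normals(g$tmax[i, j, ], g$tmin[i, j, ], g$ptotal[i, j, ],
                  g$rh09[i, j, ], g$rh15[i, j, ],
                  lon = g$lon[j], lat = g$lat[i],
                  label = sprintf("cell_%d_%d", i, j))
}

#' Run the ecoclimatic model over a climate grid
#'
#' Vectorized compare-locations run: all land cells share the weekly
#' interpolation weights, the soil-moisture fixed point is iterated over
#' the whole cell matrix at once, and stresses are accumulated per cell.
#' Masked cells carry NA in every output layer.
#'
#' @param g A [climate_grid()].
#' @param p A [species_parameters()] object.
#' @param h A [hydro_constants()] object.
#' @return A `suitability_raster`: matrices `ei`, `gi_annual`, `cs`, `hs`,
#'   `ds`, `ws`, integer `class_code` (0 unsuitable .. 3 very suitable)
#'   and character `limiting` per cell, plus the grid geometry.
#' @export
run_grid <- function(g, p, h = hydro_constants()) {
  idx <- which(g$mask, arr.ind = TRUE)
  ncell <- nrow(idx)
  shape <- function(fill) matrix(fill, length(g$lat), length(g$lon))
  out <- list(ei = shape(NA_real_), gi_annual = shape(NA_real_),
              cs = shape(NA_real_), hs = shape(NA_real_),
              ds = shape(NA_real_), ws = shape(NA_real_),
              class_code = shape(NA_integer_),
              limiting = shape(NA_character_))
  if (ncell > 0L) {
    # monthly matrices: 12 x ncell
    take <- function(v) {
      m <- matrix(NA_real_, 12, ncell)
      for (k in 1:12) m[k, ] <- g[[v]][cbind(idx, k)]
      m
    }
    tmax_m <- take("tmax"); tmin_m <- take("tmin"); p_m <- take("ptotal")
    rh_m <- (take("rh09") + take("rh15")) / 2
    tmin_w <- .W_weekly %*% tmin_m
    tmax_w <- .W_weekly %*% tmax_m
    tmean_w <- (tmin_w + tmax_w) / 2
    rh_w <- .W_weekly %*% rh_m
    rate <- .W_weekly %*% (p_m / .month_days * .week_len)
    tot <- colSums(p_m); rs <- colSums(rate)
    scale <- ifelse(tot > 0 & rs > 0, tot / rs, 1)
    rain_w <- sweep(rate, 2, scale, `*`)
    demand <- h$k_e * pmax(tmean_w, 0) * (1 - rh_w / 100)
    sm_w <- .sm_fixed_point(rain_w, demand, h)
    ti <- matrix(temperature_index(tmean_w, p), 52, ncell)
    mi <- matrix(moisture_index(sm_w, p), 52, ncell)
    gi_annual <- 100 * colMeans(ti * mi)
    # first pmax argument must be the matrix: pmax takes attributes
    # (including dim) from its first argument
    exc <- list(cold = pmax(p$ttcs - tmin_w, 0),
                heat = pmax(tmean_w - p$tths, 0),
                dry  = pmax(p$smds - sm_w, 0),
                wet  = pmax(sm_w - p$smws, 0))
    rates <- c(cold = p$thcs, heat = p$thhs, dry = p$hds, wet = p$hws)
    totals <- vapply(names(exc), function(s) {
      e <- exc[[s]]
      runs <- apply(e, 2, stress_run_lengths)
      colSums(rates[[s]] * e * runs)
    }, numeric(ncell))
    totals <- matrix(totals, ncell, 4,
                     dimnames = list(NULL, names(exc)))
    surv <- pmax(1 - pmin(totals, 1), 0)
    si <- surv[, "cold"] * surv[, "heat"] * surv[, "dry"] * surv[, "wet"]
    ei <- gi_annual * si
    lim <- apply(totals, 1, function(tt)
      if (all(tt == 0)) "none" else names(tt)[which.max(tt)])
    cells <- idx
    out$ei[cells] <- ei
    out$gi_annual[cells] <- gi_annual
    out$cs[cells] <- totals[, "cold"]
    out$hs[cells] <- totals[, "heat"]
    out$ds[cells] <- totals[, "dry"]
    out$ws[cells] <- totals[, "wet"]
    out$class_code[cells] <- as.integer(classify_suitability(ei)) - 1L
    out$limiting[cells] <- lim
  }
  structure(c(list(lon = g$lon, lat = g$lat, resolution = g$resolution,
                   mask = g$mask, region = g$region,
                   species = p$species_name), out),
            class = "suitability_raster")
}

#' @export
print.suitability_raster <- function(x, ...) {
  n <- sum(x$mask)
  cat(sprintf("Suitability raster: %d x %d cells, %d land cells%s\n",
              length(x$lat), length(x$lon), n,
              if (nzchar(x$species %||% "")) paste0(" (", x$species, ")") else ""))
  if (n > 0) {
    ei <- x$ei[x$mask]
    cat(sprintf("  EI: min %.1f, median %.1f, max %.1f; suitable (EI >= 1): %.1f%% of land cells\n",
                min(ei), stats::median(ei), max(ei), 100 * mean(ei >= 1)))
    tab <- table(factor(.suitability_levels[x$class_code[x$mask] + 1L],
                        levels = .suitability_levels))
    cat("  classes:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
summary.suitability_raster <- function(object, ...) {
  print(object)
  if (sum(object$mask) > 0) {
    lim <- table(object$limiting[object$mask])
    cat("  limiting factors:",
        paste(sprintf("%s %d", names(lim), lim), collapse = ", "), "\n")
  }
  invisible(object)
}

#' @export
as.data.frame.suitability_raster <- function(x, ...) {
  idx <- which(x$mask, arr.ind = TRUE)
  data.frame(lon = x$lon[idx[, 2]], lat = x$lat[idx[, 1]],
             region = if (!is.null(x$region)) x$region[idx] else NA_character_,
             ei = x$ei[idx], gi_annual = x$gi_annual[idx],
             cs = x$cs[idx], hs = x$hs[idx], ds = x$ds[idx], ws = x$ws[idx],
             suitability = .suitability_levels[x$class_code[idx] + 1L],
             limiting_stress = x$limiting[idx],
             stringsAsFactors = FALSE)
}

#' Plot a suitability raster
#'
#' Images the EI surface (or another layer) with masked cells blank.
#'
#' @param x A `suitability_raster`.
#' @param layer Layer name (default `"ei"`).
#' @param ... Passed to [graphics::image()].
#' @export
plot.suitability_raster <- function(x, layer = "ei", ...) {
  z <- t(x[[layer]][rev(seq_along(x$lat)), , drop = FALSE])
  graphics::image(x = x$lon, y = rev(x$lat), z = z,
                  xlab = "Longitude", ylab = "Latitude",
                  main = paste("Layer:", layer), ...)
  invisible(x)
}
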