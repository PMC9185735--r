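#' Monthly climate normals for one location
#'
#' Long-term monthly means of the five driving variables: daily maximum and
#' minimum temperature (degrees C), total precipitation (mm), and relative
#' humidity at 09:00 and 15:00 (percent) — the layout of 10-arc-minute
#' interpolated climate surfaces such as CliMond CM10.
#'
#' @param tmax,tmin Numeric length-12, degrees C, `tmax >= tmin` monthwise.
#' @param ptotal Numeric length-12, monthly precipitation totals (mm, >= 0).
#' @param rh09,rh15 Numeric length-12, percent in \[0, 100\].
#' @param lon,lat Location, degrees east in \[-180, 180) / north in \[-90, 90\].
#' @param label Free-text station / cell label.
#' @return An object of class `climate_normals`.
#' @export
climate_normals <- function(tmax, tmin, ptotal, rh09, rh15,
                            lon = NA_real_, lat = NA_real_, label = "") {
  n <- structure(list(tmax = as.numeric(tmax), tmin = as.numeric(tmin),
                      ptotal = as.numeric(ptotal), rh09 = as.numeric(rh09),
                      rh15 = as.numeric(rh15),
                      lon = as.numeric(lon), lat = as.numeric(lat),
                      label = as.character(label)),
                 class = "climate_normals")
  viol <- validate_normals(n)
  if (length(viol))
    stop_validation("invalid climate normals%s: %s",
                    if (nzchar(label)) paste0(" (", label, ")") else "",
                    paste(viol, collapse = "; "))
  n
}

validate_normals <- function(n) {
  v <- character(0)
  for (f in c("tmax", "tmin", "ptotal", "rh09", "rh15"))
    if (length(n[[f]]) != 12L || anyNA(n[[f]]))
      v <- c(v, sprintf("%s must be 12 non-missing monthly values", f))
  if (length(v)) return(v)
  bad <- which(n$tmax < n$tmin)
  if (length(bad))
    v <- c(v, sprintf("tmax < tmin in month %s", paste(bad, collapse = ",")))
  if (any(n$ptotal < 0)) v <- c(v, "ptotal must be >= 0")
  for (f in c("rh09", "rh15"))
    if (any(n[[f]] < 0 | n[[f]] > 100))
      v <- c(v, sprintf("%s outside [0, 100]", f))
  v
}

#' @export
print.climate_normals <- function(x, ...) {
  cat("Monthly climate normals:", if (nzchar(x$label)) x$label else "(unlabelled)",
      sprintf(" [lon %.3f, lat %.3f]\n", x$lon, x$lat))
  m <- rbind(tmax = x$tmax, tmin = x$tmin, ptotal = x$ptotal,
             rh09 = x$rh09, rh15 = x$rh15)
  colnames(m) <- month.abb
  print(round(m, 1))
  invisible(x)
}

# 63-column station CSV layout: label, lon, lat, then <var>_<month> for
# var in tmax, tmin, ptotal, rh09, rh15 and month 1..12.
.station_columns <- function() {
  vars <- c("tmax", "tmin", "ptotal", "rh09", "rh15")
  c("label", "lon", "lat",
    as.vector(t(outer(vars, 1:12, function(v, m) paste0(v, "_", m)))))
}

#' Read station climate normals from CSV
#'
#' Expects one row per location with columns `label`, `lon`, `lat` and the
#' 60 monthly columns `tmax_1..tmax_12`, `tmin_1..tmin_12`,
#' `ptotal_1..ptotal_12`, `rh09_1..rh09_12`, `rh15_1..rh15_12`.
#'
#' @param path CSV file path.
#' @return A list of [climate_normals()] objects. An empty file (header
#'   only) yields an empty list with a warning.
#' @export
read_station_normals <- function(path) {
  if (!file.exists(path)) stop_io("station CSV not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- .station_columns()
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_validation("station CSV missing column(s): %s",
                    paste(missing, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("station CSV contains no rows: ", path)
    return(list())
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    grab <- function(v) as.numeric(row[paste0(v, "_", 1:12)])
    tryCatch(
      climate_normals(grab("tmax"), grab("tmin"), grab("ptotal"),
                      grab("rh09"), grab("rh15"),
                      lon = row$lon, lat = row$lat, label = row$label),
      ecoclim_validation_error = function(e) {
        tmax <- grab("tmax"); tmin <- grab("tmin")
        bad <- which(!is.na(tmax) & !is.na(tmin) & tmax < tmin)
        detail <- if (length(bad))
          sprintf(" (tmax < tmin in %s)", paste(month.abb[bad], collapse = ", "))
        else ""
        stop_validation("row %d of %s invalid%s: %s", i, path, detail,
                        conditionMessage(e))
      })
  })
}

#' Write station climate normals to CSV
#'
#' Inverse of [read_station_normals()]; the round trip is an identity.
#'
#' @param normals A [climate_normals()] object or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_station_normals <- function(normals, path) {
  if (inherits(normals, "climate_normals")) normals <- list(normals)
  rows <- lapply(normals, function(n) {
    vals <- c(list(label = n$label, lon = n$lon, lat = n$lat),
              as.list(c(n$tmax, n$tmin, n$ptotal, n$rh09, n$rh15)))
    names(vals) <- .station_columns()
    as.data.frame(vals, check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# --- weekly time base ------------------------------------------------------
# 52 equal weeks of 365.25/52 = 7.024 days; month midpoints at the
# cumulative-day centres of a 365.25-day calendar (February = 28.25 d).

.month_days <- c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
.month_mid <- cumsum(.month_days) - .month_days / 2
.week_len <- 365.25 / 52
.week_mid <- (seq_len(52) - 0.5) * .week_len

# periodic piecewise-linear interpolation from 12 monthly values to the 52
# week midpoints, as a 52 x 12 weight matrix (same for every variable/cell)
.weekly_weights <- function() {
  x <- c(.month_mid - 365.25, .month_mid, .month_mid + 365.25)
  W <- matrix(0, 52, 12)
  for (m in seq_len(36)) {
    basis <- numeric(36); basis[m] <- 1
    W[, (m - 1L) %% 12L + 1L] <- W[, (m - 1L) %% 12L + 1L] +
      stats::approx(x, basis, xout = .week_mid)$y
  }
  W
}
.W_weekly <- .weekly_weights()

#' Interpolate monthly normals to a 52-week series
#'
#' Temperatures and humidity are interpolated piecewise-linearly between
#' successive month midpoints with annual wrap-around; precipitation is
#' first converted to a weekly rate (mm/week), interpolated the same way,
#' then rescaled so the 52 weekly values sum exactly to the annual total.
#' Weekly relative humidity is the mean of the 09:00 and 15:00 normals.
#' Soil moisture (`sm`) and evaporative demand (`evap`) are left unset; see
#' [soil_moisture_series()].
#'
#' @param n A [climate_normals()] object.
#' @return A `weekly_series` data frame with 52 rows and columns `week`,
#'   `tmin`, `tmax`, `tmean`, `rain` (mm/week), `rh` (percent), `evap`,
#'   `sm`.
#' @export
interpolate_weekly <- function(n) {
  viol <- validate_normals(n)
  if (length(viol))
    stop_validation("invalid climate normals: %s", paste(viol, collapse = "; "))
  tmin <- as.vector(.W_weekly %*% n$tmin)
  tmax <- as.vector(.W_weekly %*% n$tmax)
  rate <- as.vector(.W_weekly %*% (n$ptotal / .month_days * .week_len))
  total <- sum(n$ptotal)
  rain <- if (total > 0 && sum(rate) > 0) rate * total / sum(rate) else rate
  rh <- as.vector(.W_weekly %*% ((n$rh09 + n$rh15) / 2))
  ws <- data.frame(week = seq_len(52), tmin = tmin, tmax = tmax,
                   tmean = (tmin + tmax) / 2, rain = rain, rh = rh,
                   evap = NA_real_, sm = NA_real_)
  class(ws) <- c("weekly_series", "data.frame")
  attr(ws, "label") <- n$label
  attr(ws, "lon") <- n$lon
  attr(ws, "lat") <- n$lat
  ws
}

#' Hydrological constants for the weekly soil-moisture bucket
#'
#' The bucket holds `capacity` mm at field capacity (soil moisture
#' fraction 1) and can temporarily exceed it up to `sm_cap` (waterlogging).
#' Weekly evaporative demand is `k_e * max(tmean, 0) * (1 - rh/100)` mm;
#' actual evapotranspiration is demand scaled by `min(sm, 1)` (moisture
#' limited). Water above field capacity drains at the fraction `k_d` per
#' week. The default `k_e = 7` makes warm-tropics annual demand roughly
#' 1500 mm, a standard potential-evapotranspiration magnitude.
#'
#' @param k_e Demand coefficient, mm per degree C per week (default 7).
#' @param capacity Field capacity of the bucket, mm (default 100).
#' @param k_d Weekly drainage fraction of water above field capacity
#'   (default 0.2).
#' @param sm_cap Ceiling on the soil-moisture fraction (default 2.5, so
#'   that wet-stress thresholds up to 1.7 are reachable).
#' @param tol Fixed-point tolerance on the periodic annual cycle
#'   (default 1e-9, comfortably below the 1e-6 the model guarantees).
#' @param max_cycles Maximum annual iterations before giving up
#'   (default 500).
#' @return An object of class `hydro_constants`.
#' @export
hydro_constants <- function(k_e = 7, capacity = 100, k_d = 0.2,
                            sm_cap = 2.5, tol = 1e-9, max_cycles = 500L) {
  if (k_e < 0 || capacity <= 0 || k_d < 0 || k_d > 1 || sm_cap <= 0)
    stop_validation("invalid hydrological constants")
  structure(list(k_e = k_e, capacity = capacity, k_d = k_d, sm_cap = sm_cap,
                 tol = tol, max_cycles = as.integer(max_cycles)),
            class = "hydro_constants")
}

# one year of the bucket recursion; sm0 is a vector over cells, rain/
# demand are 52 x ncell matrices. Returns 52 x ncell matrix.
.sm_one_year <- function(sm0, rain, demand, h) {
  out <- matrix(NA_real_, nrow(rain), ncol(rain))
  sm <- sm0
  for (w in seq_len(nrow(rain))) {
    evap <- demand[w, ] * pmin(sm, 1)
    drain <- h$k_d * h$capacity * pmax(sm - 1, 0)
    sm <- pmin(pmax(sm + (rain[w, ] - evap - drain) / h$capacity, 0), h$sm_cap)
    out[w, ] <- sm
  }
  out
}

# Iterate the annual cycle to its periodic fixed point, vectorized over
# columns (cells). Convergence is judged per cell and converged cells are
# frozen, so each cell's trajectory — and stopping cycle — is identical
# whether it is run alone or inside a grid. Errors on non-convergence.
.sm_fixed_point <- function(rain, demand, h, sm_init = 0.5) {
  nweek <- nrow(rain)
  ncell <- ncol(rain)
  out <- matrix(NA_real_, nweek, ncell)
  sm <- rep_len(sm_init, ncell)
  active <- seq_len(ncell)
  prev <- NULL
  for (cycle in seq_len(h$max_cycles)) {
    res <- .sm_one_year(sm[active], rain[, active, drop = FALSE],
                        demand[, active, drop = FALSE], h)
    out[, active] <- res
    if (!is.null(prev)) {
      delta <- vapply(seq_along(active), function(k)
        max(abs(res[, k] - prev[, k])), numeric(1))
      keep <- delta >= h$tol
      if (!any(keep)) return(out)
      prev <- res[, keep, drop = FALSE]
      active <- active[keep]
    } else {
      prev <- res
    }
    sm <- out[nweek, ]
  }
  stop_validation("soil-moisture recursion did not reach a periodic fixed point in %d cycles",
                  h$max_cycles)
}

#' Derive weekly soil moisture with the bucket model
#'
#' Fills the `evap` (mm/week evaporative demand) and `sm` (fraction of
#' field capacity) columns of a weekly series using the single-layer bucket
#' recursion `sm_w = clamp(sm_{w-1} + (rain_w - evap_w - drain_w)/capacity,
#' 0, sm_cap)`. The annual cycle is iterated to a periodic fixed point, so
#' the result is independent of initialisation.
#'
#' @param w A `weekly_series` from [interpolate_weekly()].
#' @param h A [hydro_constants()] object.
#' @param sm_init Starting soil-moisture fraction (any value in
#'   `[0, sm_cap]` converges to the same cycle).
#' @return The weekly series with `evap` and `sm` filled.
#' @export
soil_moisture_series <- function(w, h = hydro_constants(), sm_init = 0.5) {
  if (anyNA(w$rain) || anyNA(w$tmean) || anyNA(w$rh))
    stop_validation("weekly series has unset climate fields")
  demand <- h$k_e * pmax(w$tmean, 0) * (1 - w$rh / 100)
  sm <- .sm_fixed_point(matrix(w$rain, ncol = 1), matrix(demand, ncol = 1),
                        h, sm_init)
  w$evap <- demand
  w$sm <- as.vector(sm)
  w
}
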