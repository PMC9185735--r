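#' Weekly temperature index
#'
#' Trapezoidal response applied to weekly mean temperature: 0 at or below
#' `dv0`, rising linearly to 1 at `dv1`, 1 on the optimum plateau
#' `[dv1, dv2]`, falling linearly to 0 at `dv3`, and 0 at or above `dv3`
#' (closed support endpoints). A zero-width ramp (`dv0 = dv1` or
#' `dv2 = dv3`) degenerates to a step.
#'
#' @param t Temperature(s), degrees C (vectorized).
#' @param p A [species_parameters()] object.
#' @return Values in \[0, 1\].
#' @export
temperature_index <- function(t, p) {
  .trapezoid(t, p$dv0, p$dv1, p$dv2, p$dv3)
}

#' Weekly moisture index
#'
#' Trapezoidal response over `(sm0, sm1, sm2, sm3)`, analogous to
#' [temperature_index()], applied to weekly soil moisture expressed as a
#' fraction of field capacity.
#'
#' @param sm Soil-moisture fraction(s), >= 0 (vectorized).
#' @param p A [species_parameters()] object.
#' @return Values in \[0, 1\].
#' @export
moisture_index <- function(sm, p) {
  .trapezoid(sm, p$sm0, p$sm1, p$sm2, p$sm3)
}

.trapezoid <- function(x, a0, a1, a2, a3) {
  y <- numeric(length(x))
  y[x >= a1 & x <= a2] <- 1
  if (a1 > a0) {
    i <- x > a0 & x < a1
    y[i] <- (x[i] - a0) / (a1 - a0)
  }
  if (a3 > a2) {
    i <- x > a2 & x < a3
    y[i] <- (a3 - x[i]) / (a3 - a2)
  }
  y[x <= a0 | x >= a3] <- 0
  y
}

#' Consecutive-run lengths of weekly stress exceedance
#'
#' Returns, for each week, the number of successive weeks (including the
#' current one) with positive exceedance. Climate normals describe a
#' periodic year, so runs are counted cyclically across the week-52 to
#' week-1 boundary: a stress spell spanning the year end is one spell. The
#' run length resets to 0 whenever the exceedance is 0.
#'
#' @param exceedance Numeric length-52 vector of weekly exceedances (>= 0).
#' @param cyclic Count across the year boundary (default `TRUE`).
#' @return Integer length-52 vector of run lengths.
#' @export
stress_run_lengths <- function(exceedance, cyclic = TRUE) {
  n <- length(exceedance)
  pos <- exceedance > 0
  r <- integer(n)
  if (!any(pos)) return(r)
  if (all(pos)) return(seq_len(n))
  start <- if (cyclic) which(!pos)[1] else 1L
  cnt <- 0L
  for (k in seq_len(n)) {
    i <- (start + k - 2L) %% n + 1L
    cnt <- if (pos[i]) cnt + 1L else 0L
    r[i] <- cnt
  }
  r
}

#' Accumulate one climatic stress over the year
#'
#' Weekly stress is rate x exceedance x run length, where the run length is
#' the successive number of weeks with stress; the annual total is the sum
#' over weeks. The same formula serves cold, heat, dry and wet stress with
#' their own thresholds and rates.
#'
#' @param exceedance Numeric length-52: weekly exceedance beyond the stress
#'   threshold (degrees C for cold/heat, soil-moisture fraction for
#'   dry/wet).
#' @param run_length Integer length-52 from [stress_run_lengths()].
#' @param rate Weekly accumulation rate (per unit exceedance per week).
#' @return The annual stress total (>= 0; values >= 1 are lethal when
#'   combined into the Ecoclimatic Index).
#' @export
accumulate_stress <- function(exceedance, run_length, rate) {
  if (length(exceedance) != length(run_length))
    stop_validation("exceedance and run_length lengths differ")
  sum(rate * exceedance * run_length)
}

#' Weekly growth indices and stress exceedances
#'
#' Computes the weekly temperature index (on mean temperature), moisture
#' index (on soil moisture), growth index `gi = ti * mi`, and the four
#' stress exceedances with their consecutive-run lengths: cold
#' `max(0, ttcs - tmin)`, heat `max(0, tmean - tths)`, dry
#' `max(0, smds - sm)`, wet `max(0, sm - smws)`.
#'
#' @param w A `weekly_series` with `sm` filled (see
#'   [soil_moisture_series()]).
#' @param p A [species_parameters()] object.
#' @return A `weekly_indices` data frame (52 rows): `week`, `ti`, `mi`,
#'   `gi`, `cold_exc`, `heat_exc`, `dry_exc`, `wet_exc`, `cold_run`,
#'   `heat_run`, `dry_run`, `wet_run`.
#' @export
weekly_growth <- function(w, p) {
  if (anyNA(w$sm)) stop_validation("weekly series has unset soil moisture")
  ti <- temperature_index(w$tmean, p)
  mi <- moisture_index(w$sm, p)
  exc <- list(cold = pmax(0, p$ttcs - w$tmin),
              heat = pmax(0, w$tmean - p$tths),
              dry  = pmax(0, p$smds - w$sm),
              wet  = pmax(0, w$sm - p$smws))
  runs <- lapply(exc, stress_run_lengths)
  wi <- data.frame(week = w$week, ti = ti, mi = mi, gi = ti * mi,
                   cold_exc = exc$cold, heat_exc = exc$heat,
                   dry_exc = exc$dry, wet_exc = exc$wet,
                   cold_run = runs$cold, heat_run = runs$heat,
                   dry_run = runs$dry, wet_run = runs$wet)
  class(wi) <- c("weekly_indices", "data.frame")
  wi
}

#' Combine annual growth and stresses into the Ecoclimatic Index
#'
#' `EI = GI_A * prod(max(0, 1 - min(stress, 1)))` over the four stress
#' totals; the product is the stress index SI in \[0, 1\]. Any stress total
#' at or above 1 is lethal (EI = 0), and EI never exceeds the annual growth
#' index.
#'
#' @param gi_annual Annual growth index, `100 * mean(gi_w)`, in \[0, 100\].
#' @param cs,hs,ds,ws Accumulated cold, heat, dry, wet stress totals
#'   (>= 0).
#' @return A list with `ei` (in \[0, 100\]) and `si` (in \[0, 1\]).
#' @export
ecoclimatic_index <- function(gi_annual, cs, hs, ds, ws) {
  si <- prod(pmax(0, 1 - pmin(c(cs, hs, ds, ws), 1)))
  list(ei = gi_annual * si, si = si)
}

#' Suitability class of an Ecoclimatic Index value
#'
#' `EI = 0` is unsuitable, `0 < EI < 10` marginal, `10 <= EI < 20`
#' suitable, `EI >= 20` very suitable (the value 20 itself is assigned to
#' the very-suitable class). Regional area summaries use a separate
#' "climatically suitable" cutoff, `EI >= 1` by default; see
#' [regional_area_summary()].
#'
#' @param ei Ecoclimatic Index value(s) in \[0, 100\] (vectorized).
#' @return A factor with levels `unsuitable`, `marginal`, `suitable`,
#'   `very_suitable`.
#' @export
classify_suitability <- function(ei) {
  if (any(ei < 0 | ei > 100, na.rm = TRUE))
    stop_validation("EI outside [0, 100]")
  out <- ifelse(is.na(ei), NA_character_,
         ifelse(ei >= 20, "very_suitable",
         ifelse(ei >= 10, "suitable",
         ifelse(ei > 0, "marginal", "unsuitable"))))
  factor(out, levels = .suitability_levels)
}

.suitability_levels <- c("unsuitable", "marginal", "suitable", "very_suitable")

#' Run the ecoclimatic model for one location
#'
#' The compare-locations composition: monthly normals are interpolated to
#' 52 weeks, soil moisture is derived with the bucket model, weekly growth
#' indices and stress exceedances are computed, the four stresses are
#' accumulated, and the annual growth index and stress survivals combine
#' into the Ecoclimatic Index. Deterministic.
#'
#' @param n A [climate_normals()] object.
#' @param p A [species_parameters()] object.
#' @param h A [hydro_constants()] object.
#' @return An object of class `eco_location` with fields `gi_annual`,
#'   `cs`, `hs`, `ds`, `ws`, `si`, `ei`, `suitability`, `limiting_stress`,
#'   the 52-row `weekly` table (climate, soil moisture and indices), and
#'   the input `label`/`lon`/`lat`.
#' @export
#' @examples
#' p <- load_species_parameters(
#'   system.file("extdata", "heterorhabditis_indica.params", package = "ecoclim"))
#' n <- generate_archetype_normals("Af", lat = -18)
#' run_location(n, p)
run_location <- function(n, p, h = hydro_constants()) {
  w <- soil_moisture_series(interpolate_weekly(n), h)
  wi <- weekly_growth(w, p)
  cs <- accumulate_stress(wi$cold_exc, wi$cold_run, p$thcs)
  hs <- accumulate_stress(wi$heat_exc, wi$heat_run, p$thhs)
  ds <- accumulate_stress(wi$dry_exc, wi$dry_run, p$hds)
  ws <- accumulate_stress(wi$wet_exc, wi$wet_run, p$hws)
  gi_annual <- 100 * mean(wi$gi)
  comb <- ecoclimatic_index(gi_annual, cs, hs, ds, ws)
  weekly <- cbind(w[, c("week", "tmin", "tmax", "tmean", "rain", "rh",
                        "evap", "sm")],
                  wi[, setdiff(names(wi), "week")])
  structure(list(gi_annual = gi_annual, cs = cs, hs = hs, ds = ds, ws = ws,
                 si = comb$si, ei = comb$ei,
                 suitability = as.character(classify_suitability(comb$ei)),
                 limiting_stress = .limiting_stress(cs, hs, ds, ws),
                 weekly = weekly,
                 label = n$label, lon = n$lon, lat = n$lat,
                 species = p$species_name),
            class = "eco_location")
}

# the limiting factor in the per-stress map sense: the largest accumulated
# stress, or "none" when all four are zero
.limiting_stress <- function(cs, hs, ds, ws) {
  tot <- c(cold = cs, heat = hs, dry = ds, wet = ws)
  if (all(tot == 0)) "none" else names(tot)[which.max(tot)]
}

#' @export
print.eco_location <- function(x, ...) {
  cat("Ecoclimatic model result",
      if (nzchar(x$label)) paste0("for ", x$label) else "",
      if (nzchar(x$species)) paste0("(", x$species, ")") else "", "\n")
  cat(sprintf("  EI = %.1f (%s), annual GI = %.1f, stress index = %.3f\n",
              x$ei, x$suitability, x$gi_annual, x$si))
  cat(sprintf("  stresses: cold %.4f, heat %.4f, dry %.4f, wet %.4f (limiting: %s)\n",
              x$cs, x$hs, x$ds, x$ws, x$limiting_stress))
  invisible(x)
}

#' @export
summary.eco_location <- function(object, ...) {
  print(object)
  wk <- object$weekly
  grow <- sum(wk$gi > 0)
  cat(sprintf("  weeks with positive growth: %d of 52; peak weekly GI %.2f\n",
              grow, max(wk$gi)))
  cat(sprintf("  soil moisture range: %.2f-%.2f of field capacity; tmean %.1f-%.1f C\n",
              min(wk$sm), max(wk$sm), min(wk$tmean), max(wk$tmean)))
  invisible(object)
}

#' @export
as.data.frame.eco_location <- function(x, ...) {
  data.frame(label = x$label, lon = x$lon, lat = x$lat,
             gi_annual = x$gi_annual, cs = x$cs, hs = x$hs, ds = x$ds,
             ws = x$ws, si = x$si, ei = x$ei, suitability = x$suitability,
             limiting_stress = x$limiting_stress,
             stringsAsFactors = FALSE)
}

#' Plot the annual growth curve for one location
#'
#' Two panels in the style of a growth-curve figure: weekly mean
#' temperature and rainfall on top, the temperature and growth indices
#' below, with any stressful periods (from [growth_curve()]) shaded.
#'
#' @param x An `eco_location` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.eco_location <- function(x, ...) {
  wk <- x$weekly
  op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(wk$week, wk$tmean, type = "l", lwd = 2, col = "firebrick",
                 xlab = "", ylab = "Mean temperature (C)",
                 main = if (nzchar(x$label)) x$label else "Annual growth curve",
                 ...)
  graphics::par(new = TRUE)
  graphics::plot(wk$week, wk$rain, type = "h", col = "steelblue", axes = FALSE,
                 xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext("Rain (mm/week)", side = 4, line = 2.5, cex = 0.8)
  graphics::plot(wk$week, wk$gi, type = "l", lwd = 2, ylim = c(0, 1),
                 xlab = "Week", ylab = "Index")
  graphics::lines(wk$week, wk$ti, lty = 2, col = "firebrick")
  graphics::legend("topright", legend = c("GI", "TI"), lty = c(1, 2),
                   col = c("black", "firebrick"), bty = "n")
  invisible(x)
}
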