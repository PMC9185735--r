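# Shared fixtures, all built in code.

hi_params <- function() {
  load_species_parameters(
    system.file("extdata", "heterorhabditis_indica.params", package = "ecoclim"))
}

# constant climate: every month identical. Weekly rain is constant when the
# monthly totals are proportional to month length, so specify rain per week.
const_normals <- function(tmean = 27.5, diurnal = 9, rain_week = 15.4,
                          rh = 80, lon = 178, lat = -18, label = "const") {
  mdays <- c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  climate_normals(tmax = rep(tmean + diurnal / 2, 12),
                  tmin = rep(tmean - diurnal / 2, 12),
                  ptotal = rain_week * mdays / (365.25 / 52),
                  rh09 = rep(rh, 12), rh15 = rep(rh, 12),
                  lon = lon, lat = lat, label = label)
}

# constant climate that is optimal every week: tmean on the temperature
# plateau, and rain/demand balancing at soil moisture 0.4 (the moisture
# plateau): demand = 7 * 27.5 * (1 - 80/100) = 38.5 mm/week, so rain
# 15.4 mm/week gives the fixed point sm = rain/demand = 0.4.
optimal_normals <- function() const_normals()

# standard latitudes at which the archetypes are evaluated in tests
archetype_lats <- c(Af = -18, Aw = 15, BWh = 25, Csa = 38, Cfb = 50, Dfb = 50)

run_archetype <- function(code, p = hi_params(), h = hydro_constants()) {
  run_location(generate_archetype_normals(code, lat = archetype_lats[[code]]),
               p, h)
}

# random-but-valid species parameters for round-trip property tests
random_params <- function() {
  dv <- sort(stats::runif(4, -5, 45))
  dv[1] <- dv[1] - 0.5  # guard strictness of dv0 < dv1 and dv2 < dv3
  dv[4] <- dv[4] + 0.5
  sm <- sort(stats::runif(4, 0, 2.4))
  sm[1] <- sm[1] * 0.9
  sm[4] <- sm[4] + 0.1
  species_parameters(dv0 = dv[1], dv1 = dv[2], dv2 = dv[3], dv3 = dv[4],
                     sm0 = sm[1], sm1 = sm[2], sm2 = sm[3], sm3 = sm[4],
                     ttcs = dv[1] - stats::runif(1, 0, 10),
                     thcs = stats::runif(1, 1e-5, 0.1),
                     tths = dv[4] + stats::runif(1, 0, 10),
                     thhs = stats::runif(1, 1e-5, 0.1),
                     smds = sm[1] * stats::runif(1, 0.2, 1),
                     hds = stats::runif(1, 1e-5, 0.1),
                     smws = sm[4] + stats::runif(1, 0, 1),
                     hws = stats::runif(1, 1e-5, 0.1),
                     species_name = "random", notes = "property test")
}

# random plausible climate normals (seasonal sinusoid + seasonal rain)
random_normals <- function(lat = 30) {
  base <- stats::runif(1, 2, 30)
  amp <- stats::runif(1, 0, 14)
  diurnal <- stats::runif(1, 5, 15)
  phase <- cos(2 * pi * ((1:12) - 7) / 12) * sign(lat)
  tmean <- base + amp * phase
  rain_ann <- stats::runif(1, 150, 2500)
  wgt <- pmax(0.05, 1 + stats::runif(1, -0.9, 0.9) * phase)
  rh <- stats::runif(1, 40, 95)
  climate_normals(tmax = tmean + diurnal / 2, tmin = tmean - diurnal / 2,
                  ptotal = rain_ann * wgt / sum(wgt),
                  rh09 = rep(rh, 12), rh15 = rep(rh, 12),
                  lon = stats::runif(1, -180, 179), lat = lat,
                  label = "random")
}

# independent scalar oracle for the bucket: simulate n_years consecutive
# years week by week and return the final year
brute_force_sm <- function(rain, demand, h, years = 20, sm0 = 0.5) {
  sm <- sm0
  out <- numeric(52)
  for (y in seq_len(years)) {
    for (w in 1:52) {
      evap <- demand[w] * min(sm, 1)
      drain <- h$k_d * h$capacity * max(sm - 1, 0)
      sm <- min(max(sm + (rain[w] - evap - drain) / h$capacity, 0), h$sm_cap)
      out[w] <- sm
    }
  }
  out
}
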