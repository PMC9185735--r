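p_hi <- hi_params()

suit_raster <- function(layout = matrix(c("Af", "Aw", "Dfb", "BWh"), 2, 2),
                        block = 3, resolution = 1, origin = c(0, 20)) {
  run_grid(generate_grid(layout, block = block, resolution = resolution,
                         origin = origin), p_hi)
}

test_that("records sampled from suitable cells are all predicted present", {
  r <- suit_raster()
  rec <- generate_occurrences(r, n = 10, seed = 5, miss_rate = 0)
  v <- verify_occurrences(rec, r)
  expect_equal(v$fraction_predicted, 1)
  expect_equal(v$n_evaluated, 10)
  expect_true(all(v$records$ei > 0))
})

test_that("records in unsuitable cells count as missed, off-raster excluded", {
  r <- suit_raster()
  # a record dead-centre in a Dfb (EI = 0) cell and one off the raster
  dfb <- which(r$ei == 0 & r$mask, arr.ind = TRUE)[1, ]
  rec <- occurrence_records(lon = c(r$lon[dfb[2]], 90),
                            lat = c(r$lat[dfb[1]], -60),
                            source = "literature")
  v <- suppressMessages(verify_occurrences(rec, r))
  expect_equal(v$records$status, c("missed", "off_raster"))
  expect_equal(v$fraction_predicted, 0)
  expect_equal(v$n_excluded, 1)
  expect_error(verify_occurrences(occurrence_records(numeric(0), numeric(0)),
                                  r),
               "no records", class = "ecoclim_validation_error")
})

test_that("the predicted fraction is invariant under record order", {
  r <- suit_raster()
  rec <- generate_occurrences(r, n = 40, seed = 9, miss_rate = 0.2)
  v1 <- verify_occurrences(rec, r)
  set.seed(1)
  v2 <- verify_occurrences(rec[sample.int(nrow(rec)), ], r)
  expect_equal(v2$fraction_predicted, v1$fraction_predicted)
})

test_that("merging occurrence sets removes duplicate localities", {
  r <- suit_raster()
  a <- generate_occurrences(r, n = 20, seed = 1)
  b <- generate_occurrences(r, n = 7, seed = 2, source = "GBIF")
  m <- merge_occurrences(a, b)
  expect_equal(nrow(m), 27)
  expect_equal(nrow(merge_occurrences(a, a)), 20)  # self-merge is identity
  dup <- a[c(1, 1, 2), ]
  expect_equal(nrow(merge_occurrences(dup)), 2)
})

test_that("regional summaries use spherical cell areas", {
  r <- suit_raster(matrix(c("Af", "Af"), 1, 2), block = 1)
  s <- regional_area_summary(r)
  world <- s[s$region == "World", ]
  expect_equal(world$pct_suitable, 100)  # uniform rainforest, all suitable

  # all-zero raster: 0% everywhere
  r0 <- suit_raster(matrix("Dfb", 1, 2), block = 1)
  s0 <- regional_area_summary(r0)
  expect_true(all(s0$pct_suitable == 0))

  # two cells centred at 60 and 0 degrees latitude, only the equatorial
  # one suitable: the suitable share is the analytic spherical area ratio
  g <- generate_grid(matrix(c("Dfb", "Af"), 2, 1), resolution = 60,
                     origin = c(10, 60))
  r2 <- run_grid(g, p_hi)
  expect_true(r2$ei[2, 1] > 0 && r2$ei[1, 1] == 0)
  s2 <- regional_area_summary(r2)
  band <- function(lat) {
    sin(min(lat + 30, 90) * pi / 180) - sin(max(lat - 30, -90) * pi / 180)
  }
  want <- band(0) / (band(0) + band(60))
  world <- s2[s2$region == "World", ]
  expect_equal(world$pct_suitable / 100, want, tolerance = 1e-9)
})

test_that("per-region areas sum to the world total and shrink with threshold", {
  r <- suit_raster()
  s <- regional_area_summary(r)
  regions <- s[s$region != "World", ]
  world <- s[s$region == "World", ]
  expect_equal(sum(regions$total_area_mkm2), world$total_area_mkm2,
               tolerance = 1e-9)
  expect_equal(sum(regions$suitable_area_mkm2), world$suitable_area_mkm2,
               tolerance = 1e-9)
  expect_true(all(s$suitable_area_mkm2 <= s$total_area_mkm2 + 1e-12))
  prev <- regional_area_summary(r, threshold = 0)
  for (thr in c(1, 5, 20, 50)) {
    cur <- regional_area_summary(r, threshold = thr)
    expect_true(all(cur$suitable_area_mkm2 <=
                      prev$suitable_area_mkm2 + 1e-12))
    prev <- cur
  }
})

test_that("spherical cell areas agree with an independent geodesic oracle", {
  skip_if_not_installed("geosphere")
  res <- 2
  for (lat in c(0, 30, 60, 85)) {
    ours <- ecoclim:::.cell_area_km2(lat, res)
    poly <- cbind(c(-1, 1, 1, -1) * res / 2,
                  lat + c(-1, -1, 1, 1) * res / 2)
    # the oracle joins cell corners by great circles while grid cells are
    # bounded by parallels, so agreement is to O(res^2), ~1e-4 at 2 degrees
    ref <- geosphere::areaPolygon(poly, a = 6371000, f = 0) / 1e6
    expect_equal(ours, ref, tolerance = 1e-3)
  }
})

test_that("growth curves flag wet-season depressions as stressful periods", {
  # constant optimum: flat GI = 1, no stressful period
  gc0 <- growth_curve(optimal_normals(), p_hi)
  expect_equal(gc0$gi, rep(1, 52))
  expect_equal(nrow(attr(gc0, "stress_periods")), 0)

  # wet-tropical climate with a pronounced wet season: GI dips when soil
  # moisture exceeds the upper optimum during the high-rainfall weeks
  wet <- generate_archetype_normals(
    archetype_spec("Af", annual_rainfall = 3400,
                   rainfall_shape = "summer-peak", seasonal_amplitude = 2),
    lat = -18, label = "wet-tropics")
  gcw <- growth_curve(wet, p_hi)
  wet_weeks <- gcw$rain > stats::quantile(gcw$rain, 0.75)
  expect_gt(max(gcw$sm[wet_weeks]), p_hi$sm2)
  expect_lt(mean(gcw$gi[wet_weeks]), mean(gcw$gi[!wet_weeks]))
  sp <- attr(gcw, "stress_periods")
  expect_gt(sum(sp$length), 0)

  # a longer wet season yields a longer stressful period
  longer <- generate_archetype_normals(
    archetype_spec("Af", annual_rainfall = 4500,
                   rainfall_shape = "summer-peak", seasonal_amplitude = 2),
    lat = -18)
  gcl <- growth_curve(longer, p_hi)
  expect_gte(sum(attr(gcl, "stress_periods")$length), sum(sp$length))
})
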