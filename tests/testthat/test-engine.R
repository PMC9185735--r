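p_hi <- hi_params()

test_that("the temperature response is the published trapezoid", {
  expect_equal(temperature_index(25, p_hi), 1)
  expect_equal(temperature_index(30, p_hi), 1)
  expect_equal(temperature_index(18, p_hi), 0)
  expect_equal(temperature_index(33, p_hi), 0)
  expect_equal(temperature_index(21.5, p_hi), 0.5)
  expect_equal(temperature_index(31.5, p_hi), 0.5)
  expect_equal(temperature_index(c(-5, 50), p_hi), c(0, 0))
  # closed-form check along the rising ramp
  for (delta in c(0.5, 2, 4, 6.9))
    expect_equal(temperature_index(p_hi$dv1 - delta, p_hi),
                 (p_hi$dv1 - p_hi$dv0 - delta) / (p_hi$dv1 - p_hi$dv0))
})

test_that("the moisture response mirrors it over the soil-moisture block", {
  expect_equal(moisture_index(0.4, p_hi), 1)
  expect_equal(moisture_index(0.08, p_hi), 0)
  expect_equal(moisture_index(1.7, p_hi), 0)
  expect_equal(moisture_index(1.2, p_hi), 0.5)
  expect_equal(moisture_index(0.09, p_hi), 0.5)
})

test_that("single-point plateaus and zero-width ramps degenerate cleanly", {
  # dv1 = dv2 collapses the optimum to a single temperature
  q <- species_parameters(dv0 = 10, dv1 = 15, dv2 = 15, dv3 = 20,
                          sm0 = 0.1, sm1 = 0.2, sm2 = 0.2, sm3 = 0.9,
                          ttcs = 5, thcs = 1e-3, tths = 30, thhs = 1e-3,
                          smds = 0.05, hds = 1e-3, smws = 1, hws = 1e-3)
  expect_equal(temperature_index(c(10, 12.5, 15, 17.5, 20), q),
               c(0, 0.5, 1, 0.5, 0))
  expect_equal(moisture_index(0.2, q), 1)  # single-point plateau
  # zero-width ramps (shared support endpoints) act as steps
  expect_equal(ecoclim:::.trapezoid(c(9.99, 10, 15, 20, 20.01), 10, 10, 20, 20),
               c(0, 0, 1, 0, 0))
})

test_that("weekly growth flags exceedances with successive-week run lengths", {
  w <- soil_moisture_series(interpolate_weekly(optimal_normals()))
  wi <- weekly_growth(w, p_hi)
  expect_equal(wi$gi, rep(1, 52))
  expect_true(all(wi[, c("cold_exc", "heat_exc", "dry_exc", "wet_exc")] == 0))
  expect_equal(wi$gi, wi$ti * wi$mi)

  # one cold week amid warm weeks: a single exceedance of 5, run length 1
  w2 <- w
  w2$tmin[20] <- 6
  wi2 <- weekly_growth(w2, p_hi)
  expect_equal(wi2$cold_exc[20], 5)
  expect_equal(wi2$cold_run[20], 1L)
  expect_equal(sum(wi2$cold_run), 1L)

  # three consecutive cold weeks count 1, 2, 3
  w3 <- w
  w3$tmin[30:32] <- 1
  wi3 <- weekly_growth(w3, p_hi)
  expect_equal(wi3$cold_exc[30:32], rep(10, 3))
  expect_equal(wi3$cold_run[30:32], 1:3)
})

test_that("run lengths reset at zero exceedance and wrap the year boundary", {
  exc <- rep(0, 52)
  exc[c(5, 6, 9)] <- 2
  expect_equal(stress_run_lengths(exc)[c(5, 6, 7, 9)], c(1L, 2L, 0L, 1L))
  # a spell crossing New Year is one spell under periodic normals
  exc <- rep(0, 52)
  exc[c(51, 52, 1, 2)] <- 1
  r <- stress_run_lengths(exc)
  expect_equal(r[c(51, 52, 1, 2)], 1:4)
  expect_equal(stress_run_lengths(rep(1, 52)), 1:52)
  expect_equal(stress_run_lengths(rep(0, 52)), rep(0L, 52))
})

test_that("stress accumulation follows rate x exceedance x run length", {
  exc <- rep(0, 52)
  exc[10] <- 5
  expect_equal(accumulate_stress(exc, stress_run_lengths(exc), 0.0002),
               0.001, tolerance = 1e-12)
  exc <- rep(0, 52)
  exc[20:22] <- 10
  expect_equal(accumulate_stress(exc, stress_run_lengths(exc), 0.0002),
               0.012, tolerance = 1e-12)
  expect_equal(accumulate_stress(rep(0, 52), rep(0L, 52), 0.0002), 0)
})

test_that("EI combines annual growth with multiplicative stress survival", {
  expect_equal(ecoclimatic_index(73, 0, 0, 0, 0)$ei, 73)
  expect_equal(ecoclimatic_index(100, 1, 0, 0, 0)$ei, 0)
  expect_equal(ecoclimatic_index(100, 0, 2.5, 0, 0)$ei, 0)
  out <- ecoclimatic_index(50, 0.5, 0, 0, 0)
  expect_equal(out$ei, 25)
  expect_equal(out$si, 0.5)
  expect_equal(ecoclimatic_index(80, 0.5, 0.5, 0, 0)$ei, 20)
})

test_that("suitability classes follow the published cutoffs", {
  ei <- c(0, 5, 10, 15, 19, 20, 41)
  want <- c("unsuitable", "marginal", "suitable", "suitable", "suitable",
            "very_suitable", "very_suitable")
  expect_equal(as.character(classify_suitability(ei)), want)
  expect_error(classify_suitability(101), class = "ecoclim_validation_error")
})

test_that("a constant optimal climate scores EI = 100 exactly", {
  r <- run_location(optimal_normals(), p_hi)
  expect_identical(r$ei, 100)
  expect_identical(r$gi_annual, 100)
  expect_equal(c(r$cs, r$hs, r$ds, r$ws), rep(0, 4))
  expect_equal(r$suitability, "very_suitable")
  expect_equal(r$limiting_stress, "none")
})

test_that("a cold-continental climate is excluded by lethal cold stress", {
  r <- run_archetype("Dfb")
  wk <- r$weekly
  expect_gte(sum(wk$tmin <= 0), 15)  # a long sub-zero winter
  expect_gte(r$cs, 1)
  expect_identical(r$ei, 0)
  expect_equal(r$suitability, "unsuitable")
  expect_equal(r$limiting_stress, "cold")
})

test_that("run_location is deterministic", {
  n <- generate_archetype_normals("Aw", lat = 15)
  a <- run_location(n, p_hi)
  b <- run_location(n, p_hi)
  expect_identical(a, b)
})

test_that("EI is non-increasing in every stress accumulation rate", {
  set.seed(23)
  h <- hydro_constants()
  for (rep in 1:15) {
    n <- random_normals(lat = sample(c(-30, 0, 25, 45), 1))
    base <- run_location(n, p_hi, h)
    for (rate in c("thcs", "thhs", "hds", "hws")) {
      q <- p_hi
      q[[rate]] <- q[[rate]] * 3
      expect_lte(run_location(n, q, h)$ei, base$ei + 1e-12)
    }
  }
})

test_that("all indices respect their bounds on random climates", {
  set.seed(29)
  for (rep in 1:10) {
    r <- run_location(random_normals(lat = sample(c(-20, 10, 40), 1)), p_hi)
    wk <- r$weekly
    expect_true(all(wk$ti >= 0 & wk$ti <= 1))
    expect_true(all(wk$mi >= 0 & wk$mi <= 1))
    expect_true(all(wk$gi >= 0 & wk$gi <= 1))
    expect_gte(r$si, 0); expect_lte(r$si, 1)
    expect_gte(r$ei, 0)
    expect_lte(r$ei, r$gi_annual + 1e-12)
    expect_lte(r$gi_annual, 100)
    expect_true(all(c(r$cs, r$hs, r$ds, r$ws) >= 0))
  }
})

test_that("result methods print, summarise and convert", {
  r <- run_archetype("Af")
  expect_output(print(r), "EI = ")
  expect_output(summary(r), "soil moisture range")
  df <- as.data.frame(r)
  expect_equal(df$ei, r$ei)
  expect_equal(df$suitability, "very_suitable")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(r))
})
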