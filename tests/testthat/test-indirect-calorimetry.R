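mk_trace <- function(times, vo2, vco2, on = "06:00", off = "18:00",
                     mass = 30) {
  calorimetry_trace(data.frame(time = times, vo2 = vo2, vco2 = vco2),
                    on, off, mass)
}

test_that("phase labels follow the half-open light interval", {
  t0 <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC")
  times <- t0 + c(5.99, 6, 12, 18) * 3600
  tr <- mk_trace(times, rep(3000, 4), rep(2500, 4))
  lab <- partition_cycles(tr)
  expect_equal(as.character(lab),
               c("nocturnal", "diurnal", "diurnal", "nocturnal"))
  # wrap-around schedule (lights on at night)
  tr2 <- mk_trace(times, rep(3000, 4), rep(2500, 4), on = "21:00", off = "09:00")
  expect_equal(as.character(partition_cycles(tr2)),
               c("diurnal", "diurnal", "nocturnal", "nocturnal"))
  tr3 <- mk_trace(times, rep(3000, 4), rep(2500, 4), on = "06:00", off = "06:00")
  expect_error(partition_cycles(tr3), class = "invalid_schedule")
})

test_that("a 48 h 12:12 trace splits exactly in half", {
  tr <- make_clams_trace(hours = 48, dt_min = 10, noise_sd = 0, seed = 1)
  lab <- partition_cycles(tr$trace)
  expect_equal(unname(table(lab)["diurnal"]), 144L)
  expect_equal(unname(table(lab)["nocturnal"]), 144L)
  expect_equal(length(lab), nrow(tr$trace$samples))
  expect_false(any(is.na(lab)))
})

test_that("RER is the VCO2/VO2 ratio with guarded domain", {
  expect_equal(compute_rer(3000, 3000), 1)
  expect_equal(compute_rer(3000, 2100), 0.7)
  set.seed(8)
  vo2 <- runif(50, 1000, 5000); vco2 <- runif(50, 800, 5000)
  expect_equal(compute_rer(vo2, vco2), vco2 / vo2)
  expect_error(compute_rer(0, 100), class = "undefined_rer")
})

test_that("energy expenditure equations and linearity", {
  # VO2_abs = 1 L/h at RER 1: mass 1e6 g makes vo2 (mL/kg/h) = 1
  ee <- compute_ee(vo2 = 1, vco2 = 1, body_mass_g = 1e6)
  expect_equal(ee, 5.047, tolerance = 1e-12)
  # linear in VO2 at fixed RER
  e1 <- compute_ee(3000, 2400, 30)
  e2 <- compute_ee(6000, 4800, 30)
  expect_equal(e2, 2 * e1, tolerance = 1e-12)
  # weir variant differs and uses its own coefficients
  ew <- compute_ee(1, 1, 1e6, formula = "weir")
  expect_equal(ew, 3.941 + 1.106, tolerance = 1e-12)
})

test_that("cycle summaries equal phase constants and a group-by oracle", {
  tr <- make_clams_trace(hours = 24, dt_min = 10, noise_sd = 0,
                         vo2_light = 2800, vo2_dark = 3500,
                         rer_light = 0.8, rer_dark = 0.95, seed = 2)
  sm <- summarize_cycles(tr$trace)
  expect_equal(sm$mean_vo2[sm$phase == "diurnal"], 2800)
  expect_equal(sm$mean_vo2[sm$phase == "nocturnal"], 3500)
  expect_equal(sm$mean_rer[sm$phase == "diurnal"], 0.8)
  expect_equal(sm$mean_rer[sm$phase == "nocturnal"], 0.95)

  # randomized trace vs brute-force split means
  tr2 <- make_clams_trace(hours = 36, dt_min = 15, noise_sd = 150, seed = 6)
  lab <- partition_cycles(tr2$trace)
  sm2 <- summarize_cycles(tr2$trace, lab)
  s <- tr2$trace$samples
  for (ph in c("diurnal", "nocturnal")) {
    expect_equal(sm2$mean_vo2[sm2$phase == ph], mean(s$vo2[lab == ph]))
    expect_equal(sm2$total_activity[sm2$phase == ph],
                 sum(s$activity[lab == ph]))
  }
  # whole-trace mean equals the sample-weighted mean of phase means
  w <- sm2$n_samples / sum(sm2$n_samples)
  expect_equal(sum(w * sm2$mean_vo2), mean(s$vo2))
})

test_that("nocturnal elevation in the generator is preserved by summaries", {
  tr <- make_clams_trace(noise_sd = 80, seed = 11)
  sm <- summarize_cycles(tr$trace)
  expect_gt(sm$mean_vo2[sm$phase == "nocturnal"],
            sm$mean_vo2[sm$phase == "diurnal"])
})

test_that("acclimation dropping removes the leading window", {
  tr <- make_clams_trace(hours = 48, dt_min = 60, noise_sd = 0, seed = 3)
  sm <- summarize_cycles(tr$trace, drop_acclimation_h = 24)
  expect_equal(sum(sm$n_samples), 24L)
})

test_that("calorimetry CSV + JSON round trip", {
  tr <- make_clams_trace(hours = 30, dt_min = 30, noise_sd = 0, seed = 4)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  s <- tr$trace$samples
  s$time <- format(s$time, "%Y-%m-%dT%H:%M:%S")
  write.csv(s, csv, row.names = FALSE)
  jsonlite::write_json(list(lights_on = "06:00", lights_off = "18:00",
                            body_mass_g = 30), js, auto_unbox = TRUE)
  tr2 <- read_calorimetry(csv, js)
  expect_equal(tr2$samples$vo2, tr$trace$samples$vo2)
  expect_equal(summarize_cycles(tr2), summarize_cycles(tr$trace))
})
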