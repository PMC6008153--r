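# Trace segmentation, slope extraction and the unit chain to rates.

test_that("light_schedule interleaves dark intervals", {
  sch <- light_schedule()
  expect_equal(nrow(sch), 13)
  expect_equal(sch$light, c(0, 20, 0, 50, 0, 200, 0, 500, 0, 1000, 0, 2000, 0))
  expect_true(all(sch$duration_s == 120))
  expect_equal(sum(sch$duration_s), 1560)
  expect_error(light_schedule(numeric(0)), "nonempty")
})

test_that("segmentation detects boundaries and honours a declared schedule", {
  chem <- ref_chem()
  tr <- linear_dic_trace(chem, slopes = c(0.01, -0.02, 0.01),
                         lights = c(0, 200, 0))
  auto <- segment_trace(tr)
  expect_equal(max(auto$segment), 3)
  expect_equal(unique(auto$segment_light[auto$segment == 2]), 200)
  sch <- tibble::tibble(duration_s = c(120, 120, 120), light = c(0, 200, 0))
  dec <- segment_trace(tr, sch)
  expect_equal(dec$segment, auto$segment)
  # declared transitions disagreeing with the recorded light channel
  bad <- tibble::tibble(duration_s = c(100, 140, 120), light = c(0, 200, 0))
  expect_error(segment_trace(tr, bad), "mismatch")
  long <- tibble::tibble(duration_s = rep(120, 5), light = c(0, 200, 0, 500, 0))
  expect_error(segment_trace(tr, long), "longer than the trace")
  tr2 <- tr; tr2$time_s[5] <- tr2$time_s[4]
  expect_error(segment_trace(tr2), "strictly increasing")
})

test_that("segment_slope matches exact lines and rejects short segments", {
  t <- 0:119
  s <- segment_slope(2000 - 0.05 * t, t)
  expect_equal(s$slope, -0.05, tolerance = 1e-12)
  expect_equal(s$r_squared, 1)
  expect_equal(s$n, 110)  # 10 s trimmed at 1 Hz
  # a constant segment has slope 0 and a defined (unit) r^2
  flat <- segment_slope(rep(5, 120), t)
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 1)
  expect_error(segment_slope(1:20, 1:20), "Insufficient data")
  # se agrees with lm on noisy data
  set.seed(3)
  y <- 1 + 0.02 * t + rnorm(120, 0, 0.1)
  mine <- segment_slope(y, t, trim_s = 0, min_points = 10)
  ref <- summary(lm(y ~ t))$coefficients["t", ]
  expect_equal(mine$slope, unname(ref["Estimate"]))
  expect_equal(mine$se, unname(ref["Std. Error"]))
})

test_that("trace_to_dic inverts the builder's DIC course exactly", {
  chem <- ref_chem()
  k <- ref_constants(chem)
  tr <- linear_dic_trace(chem, slopes = c(0.005, -0.03), k = k)
  dic <- trace_to_dic(tr, chem, k)$dic
  d0 <- dic_from_ph(8.05, chem, k)$dic
  expect_lt(max(abs(dic[1:120] - (d0 + 0.005 * (0:119)))), 1e-6)
  expect_error(trace_to_dic(dplyr::select(tr, -ph_t), chem, k), "ph_t")
  tr$ph_t[3] <- 11
  expect_error(trace_to_dic(tr, chem, k), "outside")
})

test_that("the unit chain converts a DIC slope to the documented rate", {
  # -0.02 umol/kg/s uptake at density 1.0352 kg/L and 2 ug/mL Chla:
  # 0.02 * 1.0352 * 3600 / 2 = 37.27 umol C / (mg Chla h)
  chem <- ref_chem()
  k <- ref_constants(chem)
  tr <- linear_dic_trace(chem, slopes = c(0, -0.02), lights = c(0, 200), k = k)
  pts <- pve_points(tr, chem, chla = 2, k = k)
  expect_equal(pts$rate_dic[pts$light == 200], 37.2672, tolerance = 1e-6)
  expect_equal(pts$rate_dic[pts$light == 0], 0, tolerance = 1e-9)
})

test_that("pve_points flags dark segments and enforces the protocol", {
  chem <- ref_chem()
  k <- ref_constants(chem)
  tr <- linear_dic_trace(chem,
                         slopes = c(0.003, -0.02, 0.003, -0.04, 0.003),
                         lights = c(0, 100, 0, 500, 0), k = k)
  pts <- pve_points(tr, chem, chla = 2, k = k)
  expect_equal(nrow(pts), 5)
  expect_equal(pts$used, c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_true(all(pts$r2_dic > 0.999999))
  # respiration is reported negative (uptake positive)
  expect_lt(pts$rate_dic[1], 0)
  expect_error(pve_points(tr, chem, chla = 0, k = k), "chla")
  lit_first <- linear_dic_trace(chem, slopes = c(-0.02, 0.003),
                                lights = c(100, 0), k = k)
  expect_error(pve_points(lit_first, chem, chla = 2, k = k),
               "dark segment")
})

test_that("oxygen rates come through the O2/Ar channel when calibrated", {
  cfg <- sim_config(seed = 11)
  tr <- simulate_trace(cfg)
  cal <- oxygen_calibration(cfg$r_sat, cfg$r_zero, cfg$chem$salinity,
                            cfg$chem$temperature)
  pts <- pve_points(tr, cfg$chem, cfg$chla, o2_cal = cal)
  expect_true(all(c("rate_o2", "se_o2", "r2_o2") %in% names(pts)))
  lit <- pts$light > 0
  # oxygen rates are PQ times the carbon rates by construction
  expect_equal(pts$rate_o2[lit] / pts$rate_dic[lit],
               rep(cfg$pq, sum(lit)), tolerance = 1e-2)
})
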