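# Spectral absorption, absorbed quanta and quantum yields.

test_that("specific_absorption applies ln(10)/(chla * path)", {
  ab <- tibble::tibble(wavelength = 400:700, value = 0.05)
  a <- specific_absorption(ab, 2000, 0.01)
  expect_equal(a$value[1], log(10) * 0.05 / (2000 * 0.01))
  expect_error(specific_absorption(ab, -1, 0.01), "> 0")
  short <- tibble::tibble(wavelength = 450:600, value = 0.05)
  expect_error(specific_absorption(short, 2000, 0.01), "400-700")
  neg <- ab; neg$value[5] <- -0.1
  expect_error(specific_absorption(neg, 2000, 0.01), ">= 0")
})

test_that("simulated spectra invert to the generating a* exactly", {
  sp <- simulate_spectrum(2000)
  a <- specific_absorption(sp, 2000, 0.01)
  truth <- attr(sp, "a_star_truth")
  expect_lt(max(abs(a$value - truth$value)), 1e-12)
  # with a seed, noise is small and reproducible
  s1 <- simulate_spectrum(2000, seed = 4)
  s2 <- simulate_spectrum(2000, seed = 4)
  expect_identical(s1$value, s2$value)
  expect_gt(max(abs(s1$value - sp$value)), 0)
})

test_that("absorbed_quanta integrates flat spectra analytically", {
  flat_a <- tibble::tibble(wavelength = 400:700, value = 0.01)
  flat_e <- tibble::tibble(wavelength = 400:700, value = 2)
  # integral of 0.01 * 2 over 300 nm = 6
  expect_equal(absorbed_quanta(flat_a, flat_e), 6, tolerance = 1e-12)
  # interpolation onto the finer grid preserves the integral
  coarse_e <- tibble::tibble(wavelength = seq(400, 700, by = 20), value = 2)
  expect_equal(absorbed_quanta(flat_a, coarse_e), 6, tolerance = 1e-10)
})

test_that("lamp spectrum is normalised to unit PAR", {
  lamp <- lamp_spectrum()
  integral <- sum(diff(lamp$wavelength) *
                    (head(lamp$value, -1) + tail(lamp$value, -1)) / 2)
  expect_equal(integral, 1, tolerance = 1e-12)
  expect_equal(lamp$wavelength[which.max(lamp$value)], 450)
})

test_that("quantum_yield applies the hours-to-seconds conversion", {
  expect_equal(quantum_yield(108, 3), (108 / 3600) / 3)
  expect_equal(quantum_yield(36, 1), 0.01)
  expect_error(quantum_yield(100, 0), "absorbed_per_s")
})

test_that("phi_series peaks at intermediate light and reports PQ", {
  lights <- c(0, 20, 50, 200, 500, 1000, 2000)
  mk <- function(scale, gas) {
    pts <- tibble::tibble(light = lights,
                          rate_dic = scale * (platt(lights, 154.79, 1.11) - 10))
    fit_platt_offset(pts, gas = gas)
  }
  fit_c <- mk(1, "carbon")
  fit_o <- mk(1.2, "oxygen")
  a_star <- attr(simulate_spectrum(2000), "a_star_truth")
  phi <- phi_series(fit_c, fit_o, a_star)
  g <- glance(phi)
  expect_equal(g$pq_at_pmax, 1.2, tolerance = 1e-6)
  # the peak sits strictly inside the grid, away from both ends
  expect_gt(g$e_at_phi_max_carbon, min(phi$light))
  expect_lt(g$e_at_phi_max_carbon, max(phi$light))
  expect_equal(g$phi_max_carbon, max(phi$phi_carbon), tolerance = 1e-12)
  expect_lt(g$phi_max_carbon, 0.125)
  # at very low light, respiration dominates: net yield is negative there
  expect_lt(phi$phi_carbon[1], phi$phi_carbon[which.max(phi$phi_carbon)])
})

test_that("phi_series guards the physical ceiling and all-respiration traces", {
  lights <- c(0, 20, 50, 200, 500, 1000, 2000)
  a_star <- attr(simulate_spectrum(2000), "a_star_truth")
  # tiny absorption cross-section drives Phi above 0.125
  weak <- a_star; weak$value <- a_star$value / 50
  pts <- tibble::tibble(light = lights,
                        rate_dic = platt(lights, 154.79, 1.11) - 10)
  fit <- fit_platt_offset(pts)
  expect_warning(phi_series(fit, a_star = weak), "ceiling")
  # respiration exceeding P_max: never net positive
  dead <- tibble::tibble(light = lights,
                         rate_dic = platt(lights, 5, 0.05) - 50)
  fit_d <- fit_platt_offset(dead)
  expect_error(phi_series(fit_d, a_star = a_star), "All-respiration")
  expect_error(phi_series(a_star = a_star), "at least one")
})

test_that("growth-based carbon rate applies the molar conversion", {
  # mu * (POC/Chla) * 1000 / 12.011
  expect_equal(growth_pchl(0.03, 175, 8.31),
               0.03 * (175 / 8.31) * 1000 / 12.011)
  expect_equal(growth_pchl(0.03, 175, 8.31), 52.6, tolerance = 1e-2)
  expect_error(growth_pchl(-0.1, 175, 8.31), ">= 0")
})
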