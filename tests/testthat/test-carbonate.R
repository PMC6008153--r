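# Carbonate engine: constants, alkalinity decomposition, speciation,
# forward/inverse pH-DIC, Tris reference and scale conversion.

test_that("equilibrium constants match the independent reference calculator", {
  k <- ref_constants()
  # frozen from an independent CO2-system implementation (Lueker K1/K2,
  # total scale, S = 35, T = 298.15 K)
  expect_equal(k$k1, 1.4218281e-06, tolerance = 1e-4)
  expect_equal(k$k2, 1.0815547e-09, tolerance = 1e-4)
  expect_equal(k$kb, 2.5265730e-09, tolerance = 1e-4)
  expect_gt(k$k1, k$k2)
})

test_that("pK1 falls with warming and constants respond to range violations", {
  k_cold <- carb_constants(medium_chemistry(35, 288.15, 2300))
  k_warm <- carb_constants(medium_chemistry(35, 298.15, 2300))
  expect_gt(-log10(k_cold$k1), -log10(k_warm$k1))
  # smooth monotone pK1 over 0-35 C
  pk1 <- vapply(seq(273.15, 308.15, by = 5), function(tk) {
    -log10(carb_constants(medium_chemistry(35, tk, 2300))$k1)
  }, numeric(1))
  expect_true(all(diff(pk1) < 0))
  expect_error(medium_chemistry(60, 298.15, 2300), "salinity")
  expect_error(medium_chemistry(35, 350, 2300), "temperature")
})

test_that("custom constant sets are pluggable and validated", {
  chem <- ref_chem()
  k <- carb_constants(chem, method = "custom", custom = list(k1 = 1.5e-6))
  expect_equal(k$k1, 1.5e-6)
  expect_equal(k$k2, ref_constants()$k2)
  expect_error(
    carb_constants(chem, method = "custom", custom = list(bogus = 1)),
    "Unknown constant"
  )
})

test_that("carbonate alkalinity strips non-carbonate terms", {
  chem <- ref_chem()
  k <- ref_constants(chem)
  # all non-carbonate totals zero at pH 7: A_c ~ A_T (hydroxide negligible)
  bare <- medium_chemistry(35, 298.15, 2000, total_borate = 0,
                           total_phosphate = 0, total_silicate = 0)
  expect_lt(abs(carbonate_alkalinity(bare, 7.0) - 2000), 1)
  # frozen independent reference at the measured-medium conditions
  expect_equal(carbonate_alkalinity(chem, 8.05, k), 1851.9252,
               tolerance = 5e-4)
  expect_lt(carbonate_alkalinity(chem, 8.05, k), chem$total_alkalinity)
  expect_error(carbonate_alkalinity(chem, 11), "6, 10")
})

test_that("speciation follows the carbonate-alkalinity partition", {
  k <- ref_constants()
  # limiting case K2 << H: by hand, CO2 = 2000e-16/1e-14 = 20, DIC ~ 2020
  k0 <- carb_constants(ref_chem(), method = "custom",
                       custom = list(k1 = 1e-6, k2 = 1e-15))
  s <- speciate_from_ph(8, 2000, k0)
  expect_equal(s$hco3, 2000, tolerance = 1e-6)
  expect_equal(s$co2, 20, tolerance = 1e-6)
  expect_equal(s$dic, 2020, tolerance = 1e-6)
  # frozen independent reference at A_c = 1900, pH 8.1
  expect_equal(speciate_from_ph(8.1, 1900, k)$dic, 1705.0107,
               tolerance = 1e-3)
  expect_error(speciate_from_ph(8, -5, k), "a_c")
})

test_that("speciation identity HCO3 + 2 CO3 = A_c holds for random draws", {
  set.seed(42)
  n <- 1000
  ph <- runif(n, 6, 10)
  a_c <- runif(n, 100, 3000)
  k1 <- 10^runif(n, -6.5, -5.5)
  k2 <- 10^runif(n, -9.5, -8.5)
  h <- 10^(-ph)
  d <- h + 2 * k2
  hco3 <- a_c * h / d
  co3 <- a_c * k2 / d
  expect_lt(max(abs(hco3 + 2 * co3 - a_c) / a_c), 1e-10)
  # and through the package path with the reference constants
  s <- speciate_from_ph(runif(200, 6, 10), runif(200, 100, 3000),
                        ref_constants())
  expect_lt(max(abs(s$hco3 + 2 * s$co3 - s$a_c) / s$a_c), 1e-10)
})

test_that("dic_from_ph composes and is monotone decreasing in pH", {
  chem <- ref_chem()
  k <- ref_constants(chem)
  s <- dic_from_ph(8.05, chem, k)
  expect_equal(s$a_c, carbonate_alkalinity(chem, 8.05, k))
  ph <- seq(7.5, 8.5, by = 0.01)
  expect_true(all(diff(dic_from_ph(ph, chem, k)$dic) < 0))
})

test_that("ph_from_dic inverts dic_from_ph across the working range", {
  chem <- ref_chem()
  k <- ref_constants(chem)
  ph <- seq(6.5, 9.5, by = 0.25)
  dic <- dic_from_ph(ph, chem, k)$dic
  expect_lt(max(abs(ph_from_dic(dic, chem, k) - ph)), 1e-8)
  # low-DIC target sits near the upper bracket and still converges
  lo <- dic_from_ph(9.9, chem, k)$dic
  expect_lt(abs(dic_from_ph(ph_from_dic(lo, chem, k), chem, k)$dic - lo),
            1e-4)
  # out-of-range target
  hi <- dic_from_ph(6, chem, k)$dic
  expect_error(ph_from_dic(hi * 1.01, chem, k), "achievable")
})

test_that("Tris buffer polynomial reproduces the certified reference", {
  expect_equal(tris_ph(35, 298.15), 8.0936, tolerance = 1e-4)
  # independent re-evaluation of the published polynomial at 15 C
  s <- 35; tk <- 288.15
  by_hand <- (11911.08 - 18.2499 * s - 0.039336 * s^2) / tk +
    (-366.27059 + 0.53993607 * s + 0.00016329 * s^2) +
    (64.52243 - 0.084041 * s) * log(tk) - 0.11149858 * tk
  expect_equal(tris_ph(35, 288.15), by_hand)
  # Tris pH falls with temperature
  tks <- seq(278, 308, by = 2)
  expect_true(all(diff(tris_ph(35, tks)) < 0))
  expect_error(tris_ph(10, 298.15), "salinity")
})

test_that("NBS-to-total conversion applies the Tris offset", {
  expect_equal(nbs_to_total(8.1, 8.0936, 8.0936), 8.1)
  expect_equal(nbs_to_total(8.1230, 8.2000, 8.0936), 8.0166)
  expect_warning(nbs_to_total(8.1, 8.7, 8.0936), "suspect")
})
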