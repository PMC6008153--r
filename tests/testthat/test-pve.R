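# P-vs-E fitting with the respiration offset.

lights7 <- c(0, 20, 50, 200, 500, 1000, 2000)

test_that("platt has the right limits and initial slope", {
  expect_equal(platt(0, 150, 1.1), 0)
  expect_equal(platt(1e6, 150, 1.1, 0), 150, tolerance = 1e-9)
  # derivative at 0 is alpha
  eps <- 1e-6
  expect_equal(platt(eps, 150, 1.1) / eps, 1.1, tolerance = 1e-5)
  # with photoinhibition the curve turns over
  p <- platt(seq(0, 5000, by = 10), 150, 1.1, beta = 5)
  expect_lt(which.max(p), length(p))
})

test_that("exact synthetic points are recovered to machine-level accuracy", {
  pts <- tibble::tibble(
    light = lights7,
    rate_dic = platt(lights7, 154.79, 1.11, 0) - 10
  )
  fit <- fit_platt_offset(pts)
  expect_equal(fit$p_max, 154.79, tolerance = 1e-6)
  expect_equal(fit$alpha, 1.11, tolerance = 1e-6)
  expect_equal(fit$beta, 0, tolerance = 1e-6)
  expect_equal(fit$respiration, 10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # predicted net curve passes back through the input points
  expect_equal(predict(fit, lights7), pts$rate_dic, tolerance = 1e-5)
})

test_that("photoinhibited points are recovered with beta > 0", {
  pts <- tibble::tibble(
    light = lights7,
    rate_dic = platt(lights7, 150, 1.2, beta = 0.5) - 12
  )
  fit <- fit_platt_offset(pts)
  expect_equal(fit$p_max, 150, tolerance = 1e-4)
  expect_equal(fit$beta, 0.5, tolerance = 1e-3)
})

test_that("negative fitted photoinhibition is clamped to zero", {
  set.seed(5)
  # noise nudges the unconstrained beta slightly negative for this draw;
  # the refit must report beta exactly 0 and still match P_max closely
  base <- platt(lights7, 150, 1.1, 0) - 10
  found <- FALSE
  for (s in 1:20) {
    set.seed(s)
    pts <- tibble::tibble(light = lights7, rate_dic = base + rnorm(7, 0, 1))
    fit <- fit_platt_offset(pts)
    expect_gte(fit$beta, 0)
    if (fit$beta == 0) found <- TRUE
  }
  expect_true(found)
})

test_that("fit input validation works", {
  pts <- tibble::tibble(light = lights7,
                        rate_dic = platt(lights7, 150, 1.1) - 10)
  expect_error(fit_platt_offset(pts[1:4, ]), "Insufficient data")
  expect_error(fit_platt_offset(pts[-1, ]), "dark")
  # used == FALSE rows are excluded from the fit
  pts2 <- dplyr::bind_rows(pts, tibble::tibble(light = 200, rate_dic = 1e6))
  pts2$used <- c(rep(TRUE, 7), FALSE)
  fit <- fit_platt_offset(pts2)
  expect_equal(fit$p_max, 150, tolerance = 1e-5)
})

test_that("tidy-masked rate column selects the oxygen channel", {
  pts <- tibble::tibble(
    light = lights7,
    rate_dic = platt(lights7, 150, 1.1) - 10,
    rate_o2 = 1.2 * (platt(lights7, 150, 1.1) - 10)
  )
  fit_o <- fit_platt_offset(pts, rate = rate_o2, gas = "oxygen")
  expect_equal(fit_o$p_max, 1.2 * 150, tolerance = 1e-4)
  expect_equal(fit_o$gas, "oxygen")
})

test_that("tanh model reports the initial slope", {
  pts <- tibble::tibble(
    light = lights7,
    rate_dic = 150 * tanh(1.1 * lights7 / 150) - 10
  )
  ts <- tanh_initial_slope(pts)
  expect_equal(ts$alpha, 1.1, tolerance = 1e-6)
  expect_equal(ts$p_m, 150, tolerance = 1e-5)
  expect_error(tanh_initial_slope(pts[1:3, ]), "Insufficient data")
})

test_that("tidy and glance follow broom conventions", {
  pts <- tibble::tibble(light = lights7,
                        rate_dic = platt(lights7, 150, 1.1) - 10)
  fit <- fit_platt_offset(pts)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term, c("p_max", "alpha", "beta", "respiration"))
  expect_true(all(c("estimate", "std.error") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$nobs, 7)
  expect_equal(gl$p_max, fit$p_max)
})
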