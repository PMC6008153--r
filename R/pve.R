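# Photosynthesis-irradiance curve fitting with a dark-respiration offset.

#' Photosynthesis-irradiance response with photoinhibition
#'
#' `P = P_max (1 - exp(-alpha I / P_max)) exp(-beta I / P_max)`, the
#' saturating exponential with an optional photoinhibition factor.
#'
#' @param light Irradiance I, umol quanta m-2 s-1.
#' @param p_max Light-saturated rate (same units as the fitted rates).
#' @param alpha Light-limited initial slope.
#' @param beta Photoinhibition parameter (>= 0; 0 disables inhibition).
#' @return Rate at each `light`.
#' @export
platt <- function(light, p_max, alpha, beta = 0) {
  p_max * (1 - exp(-alpha * light / p_max)) * exp(-beta * light / p_max)
}

.platt_starts <- function(light, rate) {
  pos <- light > 0
  io <- order(light[pos])
  l1 <- light[pos][io][1]
  a0 <- max(rate[pos][io][1] / l1, 1e-3)
  p0 <- max(rate, a0 * l1, 1e-3)
  list(alpha = a0, p_max = p0)
}

.fit_platt <- function(light, rate, fix_beta0 = FALSE) {
  st <- .platt_starts(light, rate)
  # deterministic multistart: jittered scalings of the heuristic start
  jit <- list(c(1, 1), c(0.6, 1), c(1.6, 1), c(1, 0.6), c(1, 1.6))
  dat <- data.frame(light = light, rate = rate)
  best <- NULL
  for (j in jit) {
    fit <- tryCatch({
      if (fix_beta0) {
        minpack.lm::nlsLM(
          rate ~ platt(light, p_max, alpha, 0), data = dat,
          start = list(p_max = st$p_max * j[1], alpha = st$alpha * j[2]),
          lower = c(p_max = 1e-9, alpha = 1e-9),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        )
      } else {
        minpack.lm::nlsLM(
          rate ~ platt(light, p_max, alpha, beta), data = dat,
          start = list(p_max = st$p_max * j[1], alpha = st$alpha * j[2],
                       beta = 0),
          lower = c(p_max = 1e-9, alpha = 1e-9, beta = -Inf),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        )
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    abort("Platt fit failed to converge from any start; inspect the points.")
  }
  best$fit
}

#' Fit a P-vs-E curve with the respiration-offset procedure
#'
#' The dark rate (light = 0, normally negative: respiration) is taken as an
#' offset `R = |rate(0)|` and added to every point so the data start at 0;
#' the offset points are fitted with [platt()] by nonlinear least squares
#' (deterministic multistart); and the offset is subtracted back from the
#' fitted curve on output. If the unconstrained photoinhibition parameter
#' comes out negative it is clamped to 0 and the curve refitted.
#'
#' @param points A tibble of per-segment rates (e.g. from [pve_points()]).
#'   Rows with `used == FALSE` are dropped if that column is present.
#' @param rate,light Columns holding the rate and light level
#'   (data-masked; defaults `rate_dic` and `light`).
#' @param gas Label stored on the fit (e.g. `"carbon"`, `"oxygen"`).
#' @return An object of class `pve_fit` with elements `p_max`, `alpha`,
#'   `beta`, `respiration`, `se` (named vector), `r_squared`, `gas` and the
#'   point table (`light`, `rate`, `offset_rate`, `fitted_net`).
#' @seealso [tanh_initial_slope()], [predict.pve_fit()], [tidy.pve_fit()]
#' @export
#' @examples
#' pts <- tibble::tibble(
#'   light = c(0, 20, 50, 200, 500, 1000, 2000),
#'   rate_dic = platt(c(0, 20, 50, 200, 500, 1000, 2000), 150, 1.1) - 10
#' )
#' fit_platt_offset(pts)
fit_platt_offset <- function(points, rate = rate_dic, light = light,
                             gas = "carbon") {
  points <- as_tibble(points)
  if ("used" %in% names(points)) points <- points[points$used, ]
  rate_v <- eval_tidy(enquo(rate), points)
  light_v <- eval_tidy(enquo(light), points)
  if (length(rate_v) < 5) {
    abort("Insufficient data: need >= 5 points including the dark rate.")
  }
  dark <- which(light_v == 0)
  if (!length(dark)) abort("Protocol error: no light = 0 (dark) point.")
  r_off <- abs(rate_v[dark[1]])
  shifted <- rate_v + r_off

  fit <- .fit_platt(light_v, shifted, fix_beta0 = FALSE)
  cf <- coef(fit)
  if (!"beta" %in% names(cf)) cf["beta"] <- 0
  if (cf[["beta"]] < 0) {
    fit <- .fit_platt(light_v, shifted, fix_beta0 = TRUE)
    cf <- c(coef(fit), beta = 0)
  }
  if (length(rate_v) < length(coef(fit)) + 1) {
    abort("Insufficient data: fewer points than free parameters.")
  }
  sm <- summary(fit)
  se <- setNames(rep(NA_real_, 3), c("p_max", "alpha", "beta"))
  se[rownames(sm$coefficients)] <- sm$coefficients[, "Std. Error"]
  fitted_off <- platt(light_v, cf[["p_max"]], cf[["alpha"]], cf[["beta"]])
  r2 <- 1 - sum((shifted - fitted_off)^2) /
    sum((shifted - mean(shifted))^2)
  structure(
    list(
      p_max = cf[["p_max"]], alpha = cf[["alpha"]], beta = cf[["beta"]],
      respiration = r_off, se = se, r_squared = r2, gas = gas,
      points = tibble(light = light_v, rate = rate_v,
                      offset_rate = shifted,
                      fitted_net = fitted_off - r_off)
    ),
    class = "pve_fit"
  )
}

#' Light-limited initial slope by the hyperbolic-tangent model
#'
#' Applies the same respiration offset as [fit_platt_offset()], then fits
#' `P = P_m tanh(alpha I / P_m)` to the positive-light points; the fitted
#' `alpha` is the initial slope (the curve's derivative at I = 0).
#'
#' @inheritParams fit_platt_offset
#' @return A one-row tibble: `alpha`, `p_m`, `se_alpha`, `r_squared`.
#' @export
tanh_initial_slope <- function(points, rate = rate_dic, light = light) {
  points <- as_tibble(points)
  if ("used" %in% names(points)) points <- points[points$used, ]
  rate_v <- eval_tidy(enquo(rate), points)
  light_v <- eval_tidy(enquo(light), points)
  dark <- which(light_v == 0)
  r_off <- if (length(dark)) abs(rate_v[dark[1]]) else 0
  keep <- light_v > 0
  if (sum(keep) < 3) {
    abort("Insufficient data: need >= 3 positive-light points.")
  }
  dat <- data.frame(light = light_v[keep], rate = rate_v[keep] + r_off)
  a0 <- max(dat$rate[which.min(dat$light)] / min(dat$light), 1e-3)
  p0 <- max(dat$rate)
  fit <- tryCatch(
    minpack.lm::nlsLM(rate ~ p_m * tanh(alpha * light / p_m), data = dat,
                      start = list(p_m = p0, alpha = a0),
                      lower = c(p_m = 1e-9, alpha = 1e-9)),
    error = function(e) abort(paste0("tanh fit failed: ", conditionMessage(e)))
  )
  sm <- summary(fit)
  tibble(
    alpha = coef(fit)[["alpha"]],
    p_m = coef(fit)[["p_m"]],
    se_alpha = sm$coefficients["alpha", "Std. Error"],
    r_squared = 1 - sum(residuals(fit)^2) /
      sum((dat$rate - mean(dat$rate))^2)
  )
}

#' Predict net rates from a fitted P-vs-E curve
#'
#' @param object A `pve_fit`.
#' @param light Irradiances to evaluate.
#' @param net Subtract the respiration offset (default `TRUE`); `FALSE`
#'   returns the offset (gross-like) curve.
#' @param ... Unused.
#' @return Numeric vector of rates.
#' @export
predict.pve_fit <- function(object, light, net = TRUE, ...) {
  p <- platt(light, object$p_max, object$alpha, object$beta)
  if (net) p - object$respiration else p
}

#' @export
print.pve_fit <- function(x, ...) {
  cat(sprintf("<pve_fit: %s> P_max = %.2f, alpha = %.3f, beta = %.4g, R = %.2f (r^2 = %.4f)\n",
              x$gas, x$p_max, x$alpha, x$beta, x$respiration, x$r_squared))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a P-vs-E fit
#'
#' @param x A `pve_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`,
#'   `std.error`).
#' @export
tidy.pve_fit <- function(x, ...) {
  tibble(
    term = c("p_max", "alpha", "beta", "respiration"),
    estimate = c(x$p_max, x$alpha, x$beta, x$respiration),
    std.error = c(x$se[["p_max"]], x$se[["alpha"]], x$se[["beta"]], NA_real_)
  )
}

#' One-row summary of a P-vs-E fit
#'
#' @param x A `pve_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.pve_fit <- function(x, ...) {
  tibble(
    gas = x$gas, p_max = x$p_max, alpha = x$alpha, beta = x$beta,
    respiration = x$respiration, r.squared = x$r_squared,
    nobs = nrow(x$points)
  )
}
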