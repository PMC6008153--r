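# Detection-limit statistics and the PAR-attenuation ceiling.

#' Replicate-consistency t-scores
#'
#' For each sample value, `t = (x - xbar) / (s / sqrt(n))`: the deviation of
#' one measurement from the replicate mean in units of the standard error of
#' the mean. Used per Chla level across the light steps, with the mean |t|
#' compared against a critical value at df = (number of light levels - 1).
#'
#' @param sample_values Numeric vector of replicate values (n >= 2).
#' @return Vector of t-scores, one per value.
#' @export
#' @examples
#' t_score(c(10, 12, 14))
t_score <- function(sample_values) {
  n <- length(sample_values)
  if (n < 2) abort("Need at least 2 values.")
  s <- sd(sample_values)
  if (s == 0) abort("Undefined t-score: zero variance across replicates.")
  (sample_values - mean(sample_values)) / (s / sqrt(n))
}

#' One-tailed Student-t critical value
#'
#' @param df Degrees of freedom (>= 1).
#' @param one_tailed_confidence One-tailed confidence level (e.g. 0.95).
#' @return The critical value; 1.943 at df = 6, 95 % confidence.
#' @export
#' @examples
#' critical_t(6, 0.95)
critical_t <- function(df, one_tailed_confidence = 0.95) {
  if (any(df < 1)) abort("`df` must be >= 1.")
  qt(one_tailed_confidence, df)
}

#' Minimum chlorophyll for statistically robust rates
#'
#' Fits a power law `t = c chla^(-k)` (least squares on logs) through the
#' mean-|t| versus Chla profile and solves for the Chla where the fitted
#' curve crosses the critical value: `min_chla = (c / cv)^(1 / k)`.
#'
#' @param profile Tibble with columns `chla` (ug mL-1) and `t` (mean |t|),
#'   at least 3 levels.
#' @param cv Critical value (e.g. [critical_t()] at df 6).
#' @return One-row tibble: `min_chla`, power-fit `coef_c`, `exponent_k`,
#'   `r_squared`. If the crossing lies outside the data range a warning
#'   flags the extrapolation; the extrapolated value is still returned.
#' @export
#' @examples
#' prof <- tibble::tibble(chla = c(0.5, 1, 2, 4, 8), t = 3 / c(0.5, 1, 2, 4, 8))
#' detection_limit(prof, critical_t(6, 0.95))
detection_limit <- function(profile, cv) {
  profile <- as_tibble(profile)
  if (!all(c("chla", "t") %in% names(profile))) {
    abort("`profile` needs columns `chla` and `t`.")
  }
  if (nrow(profile) < 3) abort("Need >= 3 Chla levels.")
  if (any(profile$chla <= 0) || any(profile$t <= 0)) {
    abort("`chla` and `t` must be > 0 for the power fit.")
  }
  fit <- lm(log(t) ~ log(chla), data = profile)
  k <- -coef(fit)[["log(chla)"]]
  cc <- exp(coef(fit)[["(Intercept)"]])
  min_chla <- (cc / cv)^(1 / k)
  if (min_chla < min(profile$chla) || min_chla > max(profile$chla)) {
    warn(sprintf(
      "Critical-value crossing at chla = %.3g lies outside the measured range [%.3g, %.3g]: extrapolated.",
      min_chla, min(profile$chla), max(profile$chla)
    ))
  }
  y <- log(profile$t)
  tibble(min_chla = min_chla, coef_c = cc, exponent_k = k,
         r_squared = 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2))
}

#' Fractional PAR loss from culture self-shading
#'
#' Exponential attenuation model in the measurement cuvette as a function
#' of OD750: `loss = exp(a OD750 - b)`, reported as a positive fraction of
#' the incident PAR.
#'
#' @param od750 Optical density at 750 nm, cm-1 (>= 0).
#' @param a,b Empirical attenuation coefficients (defaults: the calibrated
#'   values 9.12 and 5.61).
#' @return Fractional PAR loss (vectorised).
#' @export
#' @examples
#' attenuation_fraction(0.35)  # ~0.089, below the 10 % ceiling
attenuation_fraction <- function(od750, a = 9.12, b = 5.61) {
  if (any(od750 < 0)) abort("`od750` must be >= 0.")
  exp(a * od750 - b)
}

#' Fit the PAR-attenuation model
#'
#' Least squares of `log(loss)` on OD750, returning the coefficients of
#' [attenuation_fraction()].
#'
#' @param od_values OD750 values (>= 3 points).
#' @param measured_loss Fractional PAR losses (> 0).
#' @return One-row tibble: `a`, `b`, `r_squared`.
#' @export
fit_attenuation <- function(od_values, measured_loss) {
  if (length(od_values) < 3) abort("Insufficient data: need >= 3 points.")
  if (any(measured_loss <= 0)) abort("`measured_loss` must be > 0.")
  fit <- lm(log(measured_loss) ~ od_values)
  y <- log(measured_loss)
  tibble(a = coef(fit)[["od_values"]], b = -coef(fit)[["(Intercept)"]],
         r_squared = 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2))
}

#' OD750 ceiling for a maximum tolerated PAR loss
#'
#' Inverts [attenuation_fraction()]: `od = (b + log(max_loss)) / a`. At the
#' calibrated coefficients a 10 % ceiling corresponds to OD750 ~ 0.36,
#' adopted operationally as 0.35.
#'
#' @param a,b Attenuation coefficients.
#' @param max_loss Maximum tolerated fractional loss, in (0, 1).
#' @return OD750 ceiling, cm-1.
#' @export
#' @examples
#' max_od_for_loss(9.12, 5.61, 0.10)
max_od_for_loss <- function(a = 9.12, b = 5.61, max_loss = 0.10) {
  if (max_loss <= 0 || max_loss >= 1) abort("`max_loss` must be in (0, 1).")
  (b + log(max_loss)) / a
}
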