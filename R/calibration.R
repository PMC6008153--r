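# Electrode, ADC and oxygen calibration.

#' Fit a pH electrode calibration line
#'
#' Ordinary least squares of electrode voltage on buffer pH over the
#' calibration points (typically a 3-point NBS buffer series), with a Nernst
#' quality gate: the recovered slope magnitude must lie within
#' `pass_band` of the ideal slope `ln(10) R T / F` at the calibration
#' temperature, otherwise the electrode is rejected.
#'
#' @param buffer_points Tibble/data frame with columns `ph` (NBS buffer pH)
#'   and `voltage_mv`; at least 2 distinct buffer pH values.
#' @param temperature_k Calibration temperature, kelvin.
#' @param slope_sign Expected sign of the response slope (-1 for the usual
#'   glass-electrode wiring).
#' @param pass_band Acceptable range of `|slope| / ideal` (default
#'   `c(0.9, 1.05)`, the conventional glass-electrode criterion).
#' @return An object of class `electrode_cal` with `slope` (mV per pH),
#'   `intercept` (mV), `nernst_ratio`, the buffer table and temperature.
#' @export
#' @examples
#' b <- tibble::tibble(ph = c(4.01, 7.00, 10.01),
#'                     voltage_mv = -59.16 * c(4.01, 7.00, 10.01) + 400)
#' fit_electrode(b, 298.15)
fit_electrode <- function(buffer_points, temperature_k,
                          slope_sign = -1, pass_band = c(0.9, 1.05)) {
  buffer_points <- as_tibble(buffer_points)
  if (!all(c("ph", "voltage_mv") %in% names(buffer_points))) {
    abort("`buffer_points` needs columns `ph` and `voltage_mv`.")
  }
  if (length(unique(buffer_points$ph)) < 2) {
    abort("Singular fit: need >= 2 distinct buffer pH values.")
  }
  fit <- lm(voltage_mv ~ ph, data = buffer_points)
  slope <- coef(fit)[["ph"]]
  intercept <- coef(fit)[["(Intercept)"]]
  if (sign(slope) != sign(slope_sign)) {
    abort(sprintf("Electrode slope %.2f mV/pH has unexpected sign.", slope))
  }
  ratio <- abs(slope) / nernst_slope(temperature_k)
  if (ratio < pass_band[1] || ratio > pass_band[2]) {
    abort(sprintf(
      "Failed electrode: Nernst ratio %.3f outside [%.2f, %.2f].",
      ratio, pass_band[1], pass_band[2]
    ))
  }
  structure(
    list(slope = slope, intercept = intercept, nernst_ratio = ratio,
         buffer_points = buffer_points, temperature_k = temperature_k),
    class = "electrode_cal"
  )
}

#' @export
print.electrode_cal <- function(x, ...) {
  cat(sprintf("<electrode_cal> slope %.2f mV/pH (Nernst ratio %.3f)\n",
              x$slope, x$nernst_ratio))
  invisible(x)
}

#' Convert electrode voltage to pH
#'
#' Inverts the calibration line: `pH = (voltage - intercept) / slope`.
#' Vectorises over a full trace.
#'
#' @param voltage_mv Electrode voltage, mV (vector).
#' @param cal An [fit_electrode()] calibration.
#' @return pH on the calibration's (NBS) scale.
#' @export
voltage_to_ph <- function(voltage_mv, cal) {
  if (!inherits(cal, "electrode_cal")) abort("`cal` must be `electrode_cal`.")
  (voltage_mv - cal$intercept) / cal$slope
}

#' pH resolution of the acquisition chain
#'
#' Smallest resolvable pH step for an ADC of `mv_per_bit` behind an
#' amplifier of gain `amplifier_gain`, assuming an ideal Nernst electrode at
#' `temperature_k`: `(mv_per_bit / gain) / (ln(10) R T / F)`. At the
#' 16-bit converter's 0.1875 mV/bit and a 2.2 V/V amplifier this is
#' 0.0014 pH, i.e. a +/-0.0015 pH acquisition resolution.
#'
#' @param mv_per_bit ADC resolution, mV per bit.
#' @param amplifier_gain In-line amplifier gain, V/V.
#' @param temperature_k Temperature, kelvin.
#' @return pH units per bit.
#' @export
#' @examples
#' adc_ph_resolution(0.1875, 2.2, 298.15)
adc_ph_resolution <- function(mv_per_bit, amplifier_gain, temperature_k) {
  if (any(c(mv_per_bit, amplifier_gain, temperature_k) <= 0)) {
    abort("All inputs must be > 0.")
  }
  (mv_per_bit / amplifier_gain) / nernst_slope(temperature_k)
}

#' Oxygen solubility at air saturation
#'
#' Benson-Krause oxygen saturation concentration in equilibrium with
#' water-saturated air (Garcia & Gordon combined fit, umol kg-1), scaled
#' linearly with total pressure.
#'
#' @param salinity Practical salinity in `[0, 42]`.
#' @param temperature_k Temperature in kelvin, `[271, 313]`.
#' @param pressure_atm Total pressure, atm (default 1).
#' @return O2 saturation concentration, umol kg-1.
#' @export
#' @examples
#' oxygen_saturation(35, 283.15)
oxygen_saturation <- function(salinity, temperature_k, pressure_atm = 1) {
  if (any(salinity < 0) || any(salinity > 42)) {
    abort("`salinity` must lie in [0, 42].")
  }
  if (any(temperature_k < 271) || any(temperature_k > 313)) {
    abort("`temperature_k` must lie in [271, 313] K.")
  }
  tc <- temperature_k - 273.15
  ts <- log((298.15 - tc) / (273.15 + tc))
  a <- c(5.80871, 3.20291, 4.17887, 5.10006, -9.86643e-2, 3.80369)
  b <- c(-7.01577e-3, -7.70028e-3, -1.13864e-2, -9.51519e-3)
  c0 <- -2.75915e-7
  lnc <- a[1] + a[2] * ts + a[3] * ts^2 + a[4] * ts^3 + a[5] * ts^4 +
    a[6] * ts^5 +
    salinity * (b[1] + b[2] * ts + b[3] * ts^2 + b[4] * ts^3) +
    c0 * salinity^2
  exp(lnc) * pressure_atm
}

#' Two-point oxygen calibration for the O2/Ar signal ratio
#'
#' Stores the O2/Ar ion-current ratio at air saturation (`r_sat`) and after
#' a dithionite zero (`r_zero`) together with the saturation concentration
#' at the calibration salinity/temperature; concentrations follow by linear
#' interpolation through these two points.
#'
#' @param r_sat O2/Ar ratio of air-saturated medium.
#' @param r_zero O2/Ar ratio of oxygen-free medium (`0 <= r_zero < r_sat`).
#' @param salinity,temperature_k,pressure_atm Calibration conditions passed
#'   to [oxygen_saturation()].
#' @return An object of class `oxygen_cal`.
#' @export
oxygen_calibration <- function(r_sat, r_zero, salinity, temperature_k,
                               pressure_atm = 1) {
  if (r_zero < 0 || r_sat <= r_zero) {
    abort("Need r_sat > r_zero >= 0.")
  }
  structure(
    list(r_sat = r_sat, r_zero = r_zero,
         o2_sat = oxygen_saturation(salinity, temperature_k, pressure_atm),
         salinity = salinity, temperature_k = temperature_k),
    class = "oxygen_cal"
  )
}

#' Dissolved oxygen from the O2/Ar signal ratio
#'
#' `O2 = O2_sat (r - r_zero) / (r_sat - r_zero)`. Because both channels see
#' the same vacuum-pressure fluctuations, the ratio cancels common drift.
#' Supersaturated values (r > r_sat) are valid: photosynthesis can
#' supersaturate a closed cell.
#'
#' @param r O2/Ar signal ratio (vector).
#' @param cal An [oxygen_calibration()].
#' @return Dissolved O2, umol kg-1.
#' @export
oxygen_from_signal <- function(r, cal) {
  if (!inherits(cal, "oxygen_cal")) abort("`cal` must be `oxygen_cal`.")
  if (cal$r_sat == cal$r_zero) {
    abort("Degenerate calibration: r_sat equals r_zero.")
  }
  cal$o2_sat * (r - cal$r_zero) / (cal$r_sat - cal$r_zero)
}
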