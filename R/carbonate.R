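# Carbonate-system engine: total-scale speciation at constant alkalinity.
# Internal equilibrium math in mol/kg; the public API is umol/kg.

#' Carbonate alkalinity from total alkalinity and pH
#'
#' Strips the non-carbonate acid-base contributions from total alkalinity at
#' a known total-scale pH:
#' `A_c = A_T - [B(OH)4-] - [OH-] - [HPO4^2-] - 2[PO4^3-] - [SiO(OH)3-] + [H3PO4]`.
#' Above pH 6 the free-hydrogen term is negligible and omitted.
#'
#' @param chem A [medium_chemistry()] object (supplies A_T and the totals).
#' @param ph_t Total-scale pH, in `[6, 10]` (vectorised).
#' @param k Equilibrium constants from [carb_constants()]; computed from
#'   `chem` when `NULL`.
#' @return Carbonate alkalinity A_c in umol kg-1 (same length as `ph_t`).
#' @export
#' @examples
#' chem <- asw_medium()
#' carbonate_alkalinity(chem, 8.05)
carbonate_alkalinity <- function(chem, ph_t, k = NULL) {
  if (!inherits(chem, "medium_chemistry")) {
    abort("`chem` must be a `medium_chemistry` object.")
  }
  if (any(!is.finite(ph_t)) || any(ph_t < 6) || any(ph_t > 10)) {
    abort("`ph_t` must lie in [6, 10] (total scale).")
  }
  k <- k %||% carb_constants(chem)
  h <- 10^(-ph_t)                                   # mol/kg, total scale
  boh4 <- chem$total_borate * k$kb / (k$kb + h)      # umol/kg
  oh <- (k$kw / h) * 1e6
  dp <- h^3 + k$k1p * h^2 + k$k1p * k$k2p * h + k$k1p * k$k2p * k$k3p
  h3po4 <- chem$total_phosphate * h^3 / dp
  hpo4 <- chem$total_phosphate * k$k1p * k$k2p * h / dp
  po4 <- chem$total_phosphate * k$k1p * k$k2p * k$k3p / dp
  sioh3 <- chem$total_silicate * k$ksi / (k$ksi + h)
  a_c <- chem$total_alkalinity - boh4 - oh - hpo4 - 2 * po4 - sioh3 + h3po4
  if (any(a_c <= 0)) {
    abort("Inconsistent chemistry: carbonate alkalinity <= 0 after removing non-carbonate terms.")
  }
  a_c
}

#' Carbonate speciation at known pH and carbonate alkalinity
#'
#' Distributes carbonate alkalinity over the three dissolved inorganic carbon
#' species at a total-scale pH:
#' `[CO2] = A_c H^2 / (K1 (H + 2 K2))`, `[HCO3-] = A_c H / (H + 2 K2)`,
#' `[CO3^2-] = A_c K2 / (H + 2 K2)`, with `DIC` their sum. The identity
#' `[HCO3-] + 2[CO3^2-] = A_c` holds exactly.
#'
#' @param ph_t Total-scale pH in `[6, 10]` (vectorised).
#' @param a_c Carbonate alkalinity, umol kg-1 (> 0; recycled against `ph_t`).
#' @param k Equilibrium constants from [carb_constants()].
#' @return A tibble with columns `ph_t`, `h` (mol kg-1), `co2`, `hco3`,
#'   `co3`, `dic`, `a_c` (umol kg-1).
#' @export
#' @examples
#' k <- carb_constants(asw_medium())
#' speciate_from_ph(8.1, 1900, k)
speciate_from_ph <- function(ph_t, a_c, k) {
  if (any(a_c <= 0)) abort("`a_c` must be > 0.")
  if (any(ph_t < 6) || any(ph_t > 10)) abort("`ph_t` must lie in [6, 10].")
  if (!inherits(k, "carb_constants")) abort("`k` must be `carb_constants`.")
  h <- 10^(-ph_t)
  d <- h + 2 * k$k2
  co2 <- a_c * h^2 / (k$k1 * d)
  hco3 <- a_c * h / d
  co3 <- a_c * k$k2 / d
  tibble(
    ph_t = ph_t, h = h,
    co2 = co2, hco3 = hco3, co3 = co3,
    dic = co2 + hco3 + co3,
    a_c = a_c
  )
}

#' DIC speciation from pH at the medium's total alkalinity
#'
#' Composes [carbonate_alkalinity()] and [speciate_from_ph()]: the constant-
#' alkalinity assumption of the pH-oscillation method turns each pH sample
#' into a full speciation state.
#'
#' @inheritParams carbonate_alkalinity
#' @return A tibble as from [speciate_from_ph()].
#' @export
#' @examples
#' dic_from_ph(8.05, asw_medium())
dic_from_ph <- function(ph_t, chem, k = NULL) {
  k <- k %||% carb_constants(chem)
  speciate_from_ph(ph_t, carbonate_alkalinity(chem, ph_t, k), k)
}

#' Total-scale pH from a target DIC at constant alkalinity
#'
#' Inverts [dic_from_ph()] by bisection on pH in `[6, 10]` (DIC is strictly
#' decreasing in pH at fixed A_T), to a pH tolerance of 1e-10. Vectorised
#' over `dic`.
#'
#' @param dic Target DIC, umol kg-1.
#' @param chem A [medium_chemistry()] object.
#' @param k Optional [carb_constants()].
#' @param tol Bisection tolerance on pH.
#' @return Total-scale pH, same length as `dic`.
#' @export
#' @examples
#' chem <- asw_medium()
#' ph_from_dic(dic_from_ph(8.05, chem)$dic, chem)
ph_from_dic <- function(dic, chem, k = NULL, tol = 1e-10) {
  k <- k %||% carb_constants(chem)
  dic_of <- function(ph) dic_from_ph(ph, chem, k)$dic
  lo_dic <- dic_of(rep(10, length(dic)))  # smallest achievable DIC
  hi_dic <- dic_of(rep(6, length(dic)))   # largest achievable DIC
  bad <- dic > hi_dic | dic < lo_dic
  if (any(bad)) {
    abort(sprintf(
      "Target DIC outside the achievable range [%.1f, %.1f] umol/kg for pH in [6, 10] (first offending index %d).",
      lo_dic[1], hi_dic[1], which(bad)[1]
    ))
  }
  lo <- rep(6, length(dic))
  hi <- rep(10, length(dic))
  n_iter <- ceiling(log2(4 / tol))
  for (i in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    too_high_dic <- dic_of(mid) > dic  # mid pH too low
    lo <- ifelse(too_high_dic, mid, lo)
    hi <- ifelse(too_high_dic, hi, mid)
  }
  (lo + hi) / 2
}

#' Total-scale pH of Tris-buffered synthetic seawater
#'
#' Published polynomial for the certified Tris buffer reference as a function
#' of practical salinity and temperature (kelvin); 8.0936 at S = 35,
#' T = 298.15 K.
#'
#' @param salinity Practical salinity in `[20, 40]`.
#' @param temperature_k Temperature in kelvin, `[273, 318]`.
#' @return Total-scale pH of the buffer (vectorised).
#' @export
#' @examples
#' tris_ph(35, 298.15)
tris_ph <- function(salinity, temperature_k) {
  if (any(salinity < 20) || any(salinity > 40)) {
    abort("`salinity` must lie in [20, 40] for the Tris polynomial.")
  }
  if (any(temperature_k < 273) || any(temperature_k > 318)) {
    abort("`temperature_k` must lie in [273, 318] K.")
  }
  s <- salinity
  tk <- temperature_k
  (11911.08 - 18.2499 * s - 0.039336 * s^2) / tk +
    (-366.27059 + 0.53993607 * s + 0.00016329 * s^2) +
    (64.52243 - 0.084041 * s) * log(tk) -
    0.11149858 * tk
}

#' Convert an NBS-calibrated pH reading to the total scale
#'
#' Applies the single-point Tris correction for the liquid-junction potential
#' between laboratory buffers and seawater medium:
#' `pH_T = pH_m - (pH_m_tris - pH_cal_tris)`, where `pH_m_tris` is the
#' electrode's reading in the Tris buffer and `pH_cal_tris` its calculated
#' total-scale value ([tris_ph()]). Offsets larger than 0.5 pH are flagged as
#' a suspect calibration (warning) but still applied.
#'
#' @param ph_m Measured pH on the electrode's NBS calibration (vectorised).
#' @param ph_m_tris Measured pH of the Tris buffer on the same calibration.
#' @param ph_cal_tris Calculated total-scale Tris pH.
#' @return Total-scale pH, same length as `ph_m`.
#' @export
#' @examples
#' nbs_to_total(8.1230, 8.2000, tris_ph(35, 298.15))
nbs_to_total <- function(ph_m, ph_m_tris, ph_cal_tris) {
  offset <- ph_m_tris - ph_cal_tris
  if (abs(offset) > 0.5) {
    warn(sprintf(
      "Tris offset %.3f pH exceeds 0.5: suspect electrode calibration.",
      offset
    ))
  }
  ph_m - offset
}
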