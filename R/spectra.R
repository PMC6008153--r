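# Spectral absorption, absorbed photon flux and quantum yields.

.validate_spectrum <- function(x, name = "spectrum", nonneg = TRUE) {
  x <- as_tibble(x)
  if (!all(c("wavelength", "value") %in% names(x))) {
    abort(sprintf("`%s` needs columns `wavelength` and `value`.", name))
  }
  if (any(diff(x$wavelength) <= 0)) {
    abort(sprintf("`%s` wavelengths must be strictly increasing.", name))
  }
  if (min(x$wavelength) > 400 || max(x$wavelength) < 700) {
    abort(sprintf("`%s` must span the 400-700 nm PAR window.", name))
  }
  if (nonneg && any(x$value < -1e-12)) {
    abort(sprintf("`%s` values must be >= 0.", name))
  }
  x
}

#' Chlorophyll-specific spectral absorption coefficient
#'
#' Converts a whole-cell absorbance spectrum (integrating sphere, base-10
#' absorbance) into the Chla-specific absorption coefficient
#' `a*_ph(lambda) = ln(10) A(lambda) / ([Chla] x)`, units m2 mg-1 Chla.
#'
#' @param absorbance Spectrum tibble (`wavelength` nm, `value` = base-10
#'   absorbance) covering 400-700 nm.
#' @param chla_mg_m3 Chlorophyll a concentration, mg m-3 (> 0).
#' @param path_m Optical path length, m (> 0).
#' @return A spectrum tibble of a*_ph values.
#' @export
#' @examples
#' ab <- tibble::tibble(wavelength = 400:700, value = 0.05)
#' specific_absorption(ab, 2000, 0.01)$value[1]
specific_absorption <- function(absorbance, chla_mg_m3, path_m) {
  absorbance <- .validate_spectrum(absorbance, "absorbance")
  if (chla_mg_m3 <= 0 || path_m <= 0) {
    abort("`chla_mg_m3` and `path_m` must be > 0.")
  }
  tibble(
    wavelength = absorbance$wavelength,
    value = log(10) * absorbance$value / (chla_mg_m3 * path_m)
  )
}

#' Absorbed photon flux per unit chlorophyll
#'
#' Trapezoidal integral of `a*_ph(lambda) E0(lambda)` over 400-700 nm. The
#' two spectra are linearly interpolated onto the finer of their grids
#' before integrating.
#'
#' @param a_star Specific absorption spectrum, m2 mg-1 Chla.
#' @param e0 Spectral irradiance, umol quanta m-2 s-1 nm-1.
#' @return Absorbed flux, umol quanta mg-1 Chla s-1.
#' @export
absorbed_quanta <- function(a_star, e0) {
  a_star <- .validate_spectrum(a_star, "a_star")
  e0 <- .validate_spectrum(e0, "e0")
  grid <- if (nrow(a_star) >= nrow(e0)) a_star$wavelength else e0$wavelength
  grid <- grid[grid >= 400 & grid <= 700]
  av <- approx(a_star$wavelength, a_star$value, grid)$y
  ev <- approx(e0$wavelength, e0$value, grid)$y
  y <- av * ev
  sum(diff(grid) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Reference white-LED lamp spectral shape
#'
#' A normalised white-LED emission shape (sharp blue die peak near 450 nm
#' plus a broad phosphor band near 560 nm) on a 1-nm grid, scaled to unit
#' integral over 400-700 nm; multiplying by a PAR level in
#' umol quanta m-2 s-1 yields a spectral irradiance. Serves as the default
#' lamp when no measured spectrum is supplied.
#'
#' @param wavelength Wavelength grid, nm.
#' @return A spectrum tibble with unit PAR integral.
#' @export
lamp_spectrum <- function(wavelength = 400:700) {
  shape <- 1.0 * exp(-0.5 * ((wavelength - 450) / 10)^2) +
    0.55 * exp(-0.5 * ((wavelength - 560) / 50)^2)
  total <- sum(diff(wavelength) *
                 (head(shape, -1) + tail(shape, -1)) / 2)
  tibble(wavelength = wavelength, value = shape / total)
}

# normalise an arbitrary lamp shape to unit PAR integral
.normalise_par <- function(spec) {
  spec <- .validate_spectrum(spec, "lamp_shape")
  total <- sum(diff(spec$wavelength) *
                 (head(spec$value, -1) + tail(spec$value, -1)) / 2)
  if (total <= 0) abort("Lamp shape integrates to zero.")
  spec$value <- spec$value / total
  spec
}

#' Quantum yield from a chlorophyll-specific rate
#'
#' `Phi = (P_chl / 3600) / absorbed`: moles of C fixed (or O2 evolved) per
#' mole of photons absorbed, from an hourly chlorophyll-specific rate and
#' the absorbed photon flux per second.
#'
#' @param p_chl_per_h Net rate, umol mg-1 Chla h-1.
#' @param absorbed_per_s Absorbed flux, umol quanta mg-1 Chla s-1 (> 0).
#' @return Dimensionless quantum yield.
#' @export
#' @examples
#' quantum_yield(108, 3)
quantum_yield <- function(p_chl_per_h, absorbed_per_s) {
  if (any(absorbed_per_s <= 0)) {
    abort("Undefined yield: `absorbed_per_s` must be > 0.")
  }
  (p_chl_per_h / 3600) / absorbed_per_s
}

#' Quantum yield versus irradiance
#'
#' Evaluates the net quantum yield over a fine irradiance grid from fitted
#' P-vs-E curves and the absorbed-flux integral: for each grid irradiance E
#' the lamp shape (normalised to unit PAR) is scaled to E, giving
#' `Phi(E) = P_net(E) / (3600 integral(a* E0))`. Because net photosynthesis
#' at low light is dominated by respiration, the maximum yield `Phi_max`
#' sits at an intermediate irradiance and is reported as the peak of the
#' curve, not an initial slope. With fits for both gases the photosynthetic
#' quotient at `P_max`, `PQ = P_max(O2) / P_max(C)`, is also reported.
#'
#' @param fit_carbon,fit_oxygen `pve_fit` objects (at least one).
#' @param a_star Specific absorption spectrum, m2 mg-1 Chla.
#' @param lamp_shape Lamp spectral shape; normalised internally.
#' @param grid_step Irradiance grid step, umol quanta m-2 s-1 (default 1).
#' @return A tibble of class `phi_series` (`light`, `phi_carbon` and/or
#'   `phi_oxygen`) with attributes `phi_max`, `e_at_phi_max` (named per
#'   gas) and `pq_at_pmax`; retrieve them with [glance.phi_series()].
#' @export
phi_series <- function(fit_carbon = NULL, fit_oxygen = NULL, a_star,
                       lamp_shape = lamp_spectrum(), grid_step = 1) {
  fits <- list(carbon = fit_carbon, oxygen = fit_oxygen)
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) abort("Supply at least one `pve_fit`.")
  lamp <- .normalise_par(lamp_shape)
  absorbed_unit <- absorbed_quanta(a_star, lamp)  # per unit PAR
  lights <- fits[[1]]$points$light
  lo <- min(lights[lights > 0])
  hi <- max(lights)
  grid <- seq(lo, hi, by = grid_step)
  out <- tibble(light = grid)
  phi_max <- numeric(0)
  e_at <- numeric(0)
  any_positive <- FALSE
  for (nm in names(fits)) {
    p_net <- predict(fits[[nm]], grid, net = TRUE)
    phi <- (p_net / 3600) / (absorbed_unit * grid)
    out[[paste0("phi_", nm)]] <- phi
    pos <- which(p_net > 0)
    if (length(pos)) {
      any_positive <- TRUE
      i <- pos[which.max(phi[pos])]
      phi_max[nm] <- phi[i]
      e_at[nm] <- grid[i]
      if (phi[i] >= 0.125) {
        warn(sprintf(
          "Phi_max (%s) = %.3f exceeds the physical ceiling 0.125; check calibrations.",
          nm, phi[i]
        ))
      }
    } else {
      phi_max[nm] <- NA_real_
      e_at[nm] <- NA_real_
    }
  }
  if (!any_positive) {
    abort("All-respiration: net photosynthesis never positive over the grid.")
  }
  pq <- if (all(c("carbon", "oxygen") %in% names(fits))) {
    fits$oxygen$p_max / fits$carbon$p_max
  } else {
    NA_real_
  }
  structure(out,
            phi_max = phi_max, e_at_phi_max = e_at, pq_at_pmax = pq,
            class = c("phi_series", class(out)))
}

#' Summarise a quantum-yield series
#'
#' @param x A [phi_series()] result.
#' @param ... Unused.
#' @return A one-row tibble: `phi_max` and `e_at_phi_max` per gas present,
#'   and `pq_at_pmax`.
#' @export
glance.phi_series <- function(x, ...) {
  pm <- attr(x, "phi_max")
  ea <- attr(x, "e_at_phi_max")
  out <- tibble(.rows = 1)
  for (nm in names(pm)) {
    out[[paste0("phi_max_", nm)]] <- pm[[nm]]
    out[[paste0("e_at_phi_max_", nm)]] <- ea[[nm]]
  }
  out$pq_at_pmax <- attr(x, "pq_at_pmax")
  out
}

#' Chlorophyll-specific carbon uptake implied by growth
#'
#' Growth-based validation rate: `P_chl = mu [POC] / [Chla]`, converted from
#' g C g-1 Chla h-1 to umol C mg-1 Chla h-1 (factor 1000 / 12.011).
#'
#' @param mu_per_h Exponential (base-e) growth rate, h-1.
#' @param poc Particulate organic carbon (any mass-per-volume unit).
#' @param chla Chlorophyll a in the same unit as `poc`.
#' @return P_chl, umol C mg-1 Chla h-1.
#' @export
#' @examples
#' growth_pchl(0.03, 175, 8.31)
growth_pchl <- function(mu_per_h, poc, chla) {
  if (any(mu_per_h < 0) || any(poc <= 0) || any(chla <= 0)) {
    abort("`mu_per_h` must be >= 0 and `poc`, `chla` > 0 (same units).")
  }
  mu_per_h * (poc / chla) * 1000 / 12.011
}
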