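#' Describe the incubation medium
#'
#' Bundles the salinity, temperature and alkalinity of the seawater-based
#' culture medium together with the minor acid-base totals needed to convert
#' total alkalinity into carbonate alkalinity. All concentrations are
#' micromol per kg of solution; temperature is kelvin; density converts
#' between per-kg and per-litre quantities.
#'
#' Total borate defaults to the conservative seawater proportionality
#' 415.7 * S / 35 umol kg-1 (Uppstrom 1974). Nutrient totals default to an
#' enriched-artificial-seawater recipe (phosphate 21.8, silicate
#' 105.6 umol kg-1); pass 0 for nutrient-free media.
#'
#' @param salinity Practical salinity (0-45).
#' @param temperature Temperature in kelvin (270-315).
#' @param total_alkalinity Total alkalinity A_T, umol kg-1 (> 0).
#' @param density Medium density, kg L-1 (> 0.9).
#' @param total_borate Total boron B_T, umol kg-1; `NULL` for the salinity
#'   proportionality.
#' @param total_phosphate Total dissolved inorganic phosphorus P_T, umol kg-1.
#' @param total_silicate Total dissolved silicate Si_T, umol kg-1.
#' @return An object of class `medium_chemistry`.
#' @export
#' @examples
#' medium_chemistry(35, 298.15, total_alkalinity = 1980.1)
medium_chemistry <- function(salinity,
                             temperature,
                             total_alkalinity,
                             density = 1.0352,
                             total_borate = NULL,
                             total_phosphate = 21.8,
                             total_silicate = 105.6) {
  check_range <- function(x, lo, hi, name) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
      abort(sprintf("`%s` must be a single number in [%g, %g].", name, lo, hi))
    }
  }
  check_range(salinity, 0, 45, "salinity")
  check_range(temperature, 270, 315, "temperature")
  if (!is.numeric(total_alkalinity) || total_alkalinity <= 0) {
    abort("`total_alkalinity` must be > 0.")
  }
  if (!is.numeric(density) || density <= 0.9) {
    abort("`density` must be > 0.9 kg L-1.")
  }
  total_borate <- total_borate %||% (415.7 * salinity / 35)
  for (nm in c("total_borate", "total_phosphate", "total_silicate")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0) abort(sprintf("`%s` must be >= 0.", nm))
  }
  structure(
    list(
      salinity = salinity,
      temperature = temperature,
      total_alkalinity = total_alkalinity,
      density = density,
      total_borate = total_borate,
      total_phosphate = total_phosphate,
      total_silicate = total_silicate
    ),
    class = "medium_chemistry"
  )
}

#' @export
print.medium_chemistry <- function(x, ...) {
  cat("<medium_chemistry>\n")
  cat(sprintf("  S = %.2f, T = %.2f K (%.2f C)\n",
              x$salinity, x$temperature, x$temperature - 273.15))
  cat(sprintf("  A_T = %.1f umol/kg, density = %.4f kg/L\n",
              x$total_alkalinity, x$density))
  cat(sprintf("  B_T = %.1f, P_T = %.1f, Si_T = %.1f umol/kg\n",
              x$total_borate, x$total_phosphate, x$total_silicate))
  invisible(x)
}

#' Default artificial-seawater medium
#'
#' Convenience constructor for the enriched artificial seawater conditions of
#' a typical diatom incubation: S = 35, 25 C, A_T = 1980.1 umol kg-1 and
#' density 1.0352 kg L-1.
#'
#' @param ... Overrides passed to [medium_chemistry()].
#' @return A `medium_chemistry` object.
#' @export
asw_medium <- function(...) {
  args <- list(salinity = 35, temperature = 298.15,
               total_alkalinity = 1980.1, density = 1.0352)
  override <- list(...)
  args[names(override)] <- override
  do.call(medium_chemistry, args)
}
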