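#' Seawater acid-base equilibrium constants
#'
#' Evaluates the stoichiometric dissociation constants needed for carbonate
#' speciation at the medium's salinity and temperature, all in mol kg-1 of
#' solution on the total hydrogen-ion scale at surface pressure:
#'
#' * `k1`, `k2` carbonic acid — Lueker, Dickson & Keeling (2000);
#' * `kb` boric acid — Dickson (1990);
#' * `kw` water — Millero (1995);
#' * `k1p`, `k2p`, `k3p` phosphoric acid and `ksi` silicic acid — the
#'   standard best-practices formulations.
#'
#' The constant set is pluggable through `method`: `"lueker2000"` is the
#' built-in set; `"custom"` takes a named list of replacement values in
#' `custom` (any subset of the constants above), with the remaining members
#' evaluated from the built-in formulations.
#'
#' @param chem A [medium_chemistry()] object.
#' @param method `"lueker2000"` (default) or `"custom"`.
#' @param custom Named list of constants (mol kg-1, total scale) overriding
#'   the built-in values when `method = "custom"`.
#' @return An object of class `carb_constants`: a named list with members
#'   `k1, k2, kb, kw, k1p, k2p, k3p, ksi` plus the salinity, temperature and
#'   method they were evaluated at.
#' @export
#' @examples
#' k <- carb_constants(medium_chemistry(35, 298.15, 2300))
#' k$k1 > k$k2
carb_constants <- function(chem, method = c("lueker2000", "custom"),
                           custom = list()) {
  method <- match.arg(method)
  if (!inherits(chem, "medium_chemistry")) {
    abort("`chem` must be a `medium_chemistry` object.")
  }
  s <- chem$salinity
  tk <- chem$temperature
  if (s < 0 || s > 45) abort("`salinity` out of range [0, 45].")
  if (tk < 270 || tk > 315) abort("`temperature` out of range [270, 315] K.")
  lt <- log(tk)
  sq <- sqrt(s)

  k1 <- 10^-(3633.86 / tk - 61.2172 + 9.6777 * lt -
               0.011555 * s + 0.0001152 * s^2)
  k2 <- 10^-(471.78 / tk + 25.929 - 3.16967 * lt -
               0.01781 * s + 0.0001122 * s^2)
  kb <- exp((-8966.90 - 2890.53 * sq - 77.942 * s +
               1.728 * s^1.5 - 0.0996 * s^2) / tk +
              148.0248 + 137.1942 * sq + 1.62142 * s +
              (-24.4344 - 25.085 * sq - 0.2474 * s) * lt +
              0.053105 * sq * tk)
  kw <- exp(148.9652 - 13847.26 / tk - 23.6521 * lt +
              (118.67 / tk - 5.977 + 1.0495 * lt) * sq - 0.01615 * s)
  k1p <- exp(-4576.752 / tk + 115.525 - 18.453 * lt +
               (-106.736 / tk + 0.69171) * sq +
               (-0.65643 / tk - 0.01844) * s)
  k2p <- exp(-8814.715 / tk + 172.0883 - 27.927 * lt +
               (-160.340 / tk + 1.3566) * sq +
               (0.37335 / tk - 0.05778) * s)
  k3p <- exp(-3070.75 / tk - 18.141 +
               (17.27039 / tk + 2.81197) * sq +
               (-44.99486 / tk - 0.09984) * s)
  ion <- 19.924 * s / (1000 - 1.005 * s)
  ksi <- exp(-8904.2 / tk + 117.385 - 19.334 * lt +
               (-458.79 / tk + 3.5913) * sqrt(ion) +
               (188.74 / tk - 1.5998) * ion +
               (-12.1652 / tk + 0.07871) * ion^2 +
               log(1 - 0.001005 * s))

  k <- list(k1 = k1, k2 = k2, kb = kb, kw = kw,
            k1p = k1p, k2p = k2p, k3p = k3p, ksi = ksi)
  if (method == "custom") {
    unknown <- setdiff(names(custom), names(k))
    if (length(unknown)) {
      abort(paste0("Unknown constant(s) in `custom`: ",
                   paste(unknown, collapse = ", ")))
    }
    k[names(custom)] <- custom
  }
  if (any(unlist(k) <= 0)) abort("All equilibrium constants must be > 0.")
  if (k$k1 <= k$k2) abort("Inconsistent constants: k1 must exceed k2.")
  structure(c(k, list(salinity = s, temperature = tk, method = method)),
            class = "carb_constants")
}

#' @export
print.carb_constants <- function(x, ...) {
  cat(sprintf("<carb_constants> %s at S = %.2f, T = %.2f K\n",
              x$method, x$salinity, x$temperature))
  cat(sprintf("  pK1 = %.4f  pK2 = %.4f  pKB = %.4f  pKW = %.4f\n",
              -log10(x$k1), -log10(x$k2), -log10(x$kb), -log10(x$kw)))
  invisible(x)
}
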