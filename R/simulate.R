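# Forward simulator: synthetic traces, spectra and titrations from known
# ground truth, so every pipeline stage has a recovery oracle.

# run code with a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the forward trace simulator
#'
#' Collects the ground truth of a simulated incubation: the medium
#' chemistry, the true P-vs-E parameters of the carbon response, the
#' photosynthetic quotient tying oxygen to carbon, the biomass, the light
#' schedule, the instrument noise and the oxygen-channel calibration truth.
#'
#' @param chem A [medium_chemistry()] (defaults to [asw_medium()]).
#' @param p_max,alpha,beta True carbon P-vs-E parameters
#'   (umol C mg-1 Chla h-1 and initial-slope units).
#' @param respiration True dark respiration rate, umol C mg-1 Chla h-1
#'   (positive number; consumed in the dark).
#' @param pq True photosynthetic quotient (mol O2 per mol C).
#' @param chla Chlorophyll a, ug mL-1.
#' @param schedule Light schedule tibble ([light_schedule()]).
#' @param start_ph Initial total-scale pH, in `[7.5, 8.5]`.
#' @param sigma_ph Additive Gaussian noise on pH (sd, pH units).
#' @param sigma_signal Multiplicative Gaussian noise on each ion-current
#'   channel (fractional sd).
#' @param r_sat,r_zero True O2/Ar calibration ratios.
#' @param seed Mandatory RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chem = asw_medium(),
                       p_max = 154.79, alpha = 1.11, beta = 0,
                       respiration = 10, pq = 1.2, chla = 2,
                       schedule = light_schedule(),
                       start_ph = 8.05,
                       sigma_ph = 0, sigma_signal = 0,
                       r_sat = 10, r_zero = 0.2,
                       seed) {
  if (missing(seed)) abort("`seed` is mandatory for reproducible simulation.")
  if (start_ph < 7.5 || start_ph > 8.5) {
    abort("`start_ph` must lie in [7.5, 8.5].")
  }
  if (sigma_ph < 0 || sigma_signal < 0) abort("Noise levels must be >= 0.")
  schedule <- as_tibble(schedule)
  if (!nrow(schedule)) abort("`schedule` must be nonempty.")
  structure(
    list(chem = chem, p_max = p_max, alpha = alpha, beta = beta,
         respiration = respiration, pq = pq, chla = chla,
         schedule = schedule, start_ph = start_ph,
         sigma_ph = sigma_ph, sigma_signal = sigma_signal,
         r_sat = r_sat, r_zero = r_zero, seed = seed),
    class = "sim_config"
  )
}

#' Simulate a pH-oscillation / O2-Ar trace
#'
#' Forward model at 1 Hz: the net carbon rate at each second follows the
#' configured [platt()] response minus respiration; DIC is integrated by
#' 1-s Euler steps and converted to total-scale pH through the carbonate
#' engine at constant total alkalinity; oxygen evolves as `pq` times the
#' carbon rate from an air-saturated start and is emitted through the
#' linear two-point O2/Ar calibration truth. Gaussian noise is additive on
#' pH and multiplicative on each ion-current channel. Bit-reproducible for
#' a fixed seed.
#'
#' @param cfg A [sim_config()].
#' @return A trace tibble (`time_s`, `ph_t`, `o2_signal`, `ar_signal`,
#'   `light`, `temp_k`) with the configuration attached as attribute
#'   `truth`.
#' @export
#' @examples
#' tr <- simulate_trace(sim_config(seed = 1))
#' head(tr)
simulate_trace <- function(cfg) {
  if (!inherits(cfg, "sim_config")) abort("`cfg` must be a `sim_config`.")
  chem <- cfg$chem
  k <- carb_constants(chem)
  light <- rep(cfg$schedule$light, cfg$schedule$duration_s)
  n <- length(light)
  time_s <- seq_len(n) - 1
  net_rate <- platt(light, cfg$p_max, cfg$alpha, cfg$beta) - cfg$respiration
  # umol C mg-1 Chla h-1 -> umol kg-1 s-1 (chla ug/mL = mg/L)
  d_dic <- -net_rate * cfg$chla / chem$density / 3600
  dic0 <- dic_from_ph(cfg$start_ph, chem, k)$dic
  dic <- dic0 + cumsum(c(0, d_dic[-n]))
  rng <- dic_from_ph(c(6, 10), chem, k)$dic
  if (any(dic > max(rng)) || any(dic < min(rng))) {
    abort("Saturation: simulated pH would leave [6, 10]; shorten the run or lower `chla`.")
  }
  ph_true <- ph_from_dic(dic, chem, k)
  o2_sat <- oxygen_saturation(chem$salinity, chem$temperature)
  d_o2 <- cfg$pq * net_rate * cfg$chla / chem$density / 3600
  o2 <- o2_sat + cumsum(c(0, d_o2[-n]))
  r <- cfg$r_zero + (o2 / o2_sat) * (cfg$r_sat - cfg$r_zero)
  out <- .with_seed(cfg$seed, {
    tibble(
      time_s = time_s,
      ph_t = ph_true + rnorm(n, 0, cfg$sigma_ph),
      o2_signal = r * (1 + rnorm(n, 0, cfg$sigma_signal)),
      ar_signal = 1 + rnorm(n, 0, cfg$sigma_signal),
      light = light,
      temp_k = chem$temperature
    )
  })
  attr(out, "truth") <- cfg
  out
}

#' Simulate a whole-cell absorbance spectrum
#'
#' Builds a diatom-like specific absorption spectrum from Gaussian pigment
#' bands — the Chla Soret band near 440 nm, a carotenoid shoulder near
#' 490 nm and the Chla red band near 675 nm — scaled by a packaging factor,
#' then converts it to the base-10 absorbance a spectrophotometer would
#' record at the given Chla and path length. With a seed, small
#' multiplicative measurement noise is added; without one the spectrum is
#' exact and [specific_absorption()] inverts it to machine precision.
#'
#' @param chla_mg_m3 Chlorophyll a, mg m-3.
#' @param packaging_factor Flattening factor in (0, 1]; 1 = no packaging.
#' @param path_m Cuvette path length, m.
#' @param noise_sd Fractional measurement noise (used only with a seed).
#' @param seed Optional RNG seed.
#' @return An absorbance spectrum tibble with the generating a*_ph attached
#'   as attribute `a_star_truth`.
#' @export
simulate_spectrum <- function(chla_mg_m3, packaging_factor = 1,
                              path_m = 0.01, noise_sd = 0.003,
                              seed = NULL) {
  if (chla_mg_m3 <= 0) abort("`chla_mg_m3` must be > 0.")
  if (packaging_factor <= 0 || packaging_factor > 1) {
    abort("`packaging_factor` must be in (0, 1].")
  }
  wl <- 400:700
  band <- function(center, width, weight) {
    weight * exp(-0.5 * ((wl - center) / width)^2)
  }
  a_star <- 0.02 * packaging_factor *
    (band(440, 25, 1) + band(490, 30, 0.45) + band(675, 12, 0.55))
  absorb <- a_star * chla_mg_m3 * path_m / log(10)
  if (!is.null(seed)) {
    absorb <- .with_seed(seed, absorb * (1 + rnorm(length(wl), 0, noise_sd)))
  }
  out <- tibble(wavelength = wl, value = absorb)
  attr(out, "a_star_truth") <- tibble(wavelength = wl, value = a_star)
  out
}

#' Simulate a Gran titration
#'
#' Forward titration of a sample of known total alkalinity: acid additions
#' span 0 to 1.5x the equivalence amount; at each step the diluted
#' alkalinity and DIC are inverted for total-scale pH through the full
#' alkalinity balance. By default the titration is open-cell, as in
#' standard alkalinity practice: past the carbonate equivalence the
#' stirred, acidified sample progressively loses CO2, ramping linearly from
#' full retention at the equivalence down to a small residual once the
#' excess acid reaches `purge_span`, so the Gran window (pH < 3.8, i.e.
#' excess acid beyond ~158 umol kg-1) is free of carbonate curvature while
#' the simulated pH stays continuous through the endpoint.
#' `degas_fraction` removes that fraction of the initial DIC before
#' titrating (CO2 degassing leaves the alkalinity unchanged).
#'
#' @param true_a_t True total alkalinity, umol kg-1.
#' @param sample_mass Sample mass, g.
#' @param acid_conc Acid concentration, mol kg-1.
#' @param n_points Number of titration points.
#' @param noise_ph Gaussian pH noise (sd).
#' @param seed RNG seed.
#' @param chem Optional [medium_chemistry()] supplying S, T and totals; its
#'   alkalinity is replaced by `true_a_t`.
#' @param start_ph Initial sample pH used to set the initial DIC.
#' @param degas_fraction Fraction of initial DIC removed by degassing.
#' @param open_cell Purge CO2 from points past the equivalence (default
#'   `TRUE`); `FALSE` keeps all DIC in solution (closed cell).
#' @param residual_dic DIC remaining after full purging, umol kg-1.
#' @param purge_span Excess acid (umol kg-1 past equivalence) over which the
#'   CO2 retention ramps from 1 to the residual (default 120, below the
#'   ~158 umol kg-1 where the Gran window opens).
#' @return A [titration_record()] (gram dialect).
#' @export
#' @examples
#' gran_alkalinity(simulate_titration(2000, seed = 1))$a_t
simulate_titration <- function(true_a_t, sample_mass = 50,
                               acid_conc = 0.1723, n_points = 25,
                               noise_ph = 0, seed = 1, chem = NULL,
                               start_ph = 8.05, degas_fraction = 0,
                               open_cell = TRUE, residual_dic = 15,
                               purge_span = 120) {
  if (true_a_t <= 0) abort("`true_a_t` must be > 0.")
  chem <- chem %||% asw_medium()
  chem$total_alkalinity <- true_a_t
  k <- carb_constants(chem)
  dic0 <- dic_from_ph(start_ph, chem, k)$dic * (1 - degas_fraction)
  m_eq <- true_a_t * 1e-6 * sample_mass / acid_conc  # grams of acid
  acid <- seq(0, 1.5 * m_eq, length.out = n_points)
  dil <- sample_mass / (sample_mass + acid)
  a_t_step <- (true_a_t * sample_mass - acid_conc * acid * 1e6) /
    (sample_mass + acid)
  ph <- vapply(seq_along(acid), function(i) {
    ch <- chem
    ch$total_borate <- chem$total_borate * dil[i]
    ch$total_phosphate <- chem$total_phosphate * dil[i]
    ch$total_silicate <- chem$total_silicate * dil[i]
    solve_ph <- function(dic_i) {
      f <- function(p) .alkalinity_at_h(10^(-p), dic_i, ch, k) - a_t_step[i]
      uniroot(f, c(2, 10), tol = 1e-10)$root
    }
    dic_closed <- dic0 * dil[i]
    if (open_cell && a_t_step[i] < 0) {
      retain <- max(0, 1 + a_t_step[i] / purge_span)
      solve_ph(residual_dic + max(0, dic_closed - residual_dic) * retain)
    } else {
      solve_ph(dic_closed)
    }
  }, numeric(1))
  if (noise_ph > 0) {
    ph <- .with_seed(seed, ph + rnorm(n_points, 0, noise_ph))
  }
  titration_record(tibble(acid = acid, ph = ph),
                   sample_mass = sample_mass, acid_conc = acid_conc,
                   amount_unit = "g")
}
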