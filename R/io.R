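# CSV readers/writers, run configuration and the end-to-end pipeline.

#' Read an oscillation trace from CSV
#'
#' Expects a header row with columns `time_s`, `o2_signal`, `ar_signal`,
#' `light_umol_m2_s`, `temp_c`, plus the pH channel for the declared
#' dialect: `ph` (already total scale, or NBS needing the Tris correction)
#' or `voltage_mv` (raw electrode voltage needing a calibration). Time must
#' be strictly increasing; sampling gaps longer than 2 s are flagged.
#'
#' @param path CSV file path.
#' @param dialect `"ph_total"` (default), `"ph_nbs"` or `"voltage"`.
#' @param cal [fit_electrode()] calibration (voltage dialect).
#' @param ph_m_tris,ph_cal_tris Tris correction pair for the NBS and
#'   voltage dialects ([nbs_to_total()]).
#' @return A trace tibble with internal column names (`time_s`, `ph_t`,
#'   `o2_signal`, `ar_signal`, `light`, `temp_k`).
#' @export
read_trace_csv <- function(path, dialect = c("ph_total", "ph_nbs", "voltage"),
                           cal = NULL, ph_m_tris = NULL, ph_cal_tris = NULL) {
  dialect <- match.arg(dialect)
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time_s", "o2_signal", "ar_signal", "light_umol_m2_s", "temp_c",
            if (dialect == "voltage") "voltage_mv" else "ph")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(paste0("Trace file is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (any(diff(df$time_s) <= 0)) {
    abort(sprintf("Non-monotone time at row %d.",
                  which(diff(df$time_s) <= 0)[1] + 1))
  }
  gaps <- which(diff(df$time_s) > 2)
  if (length(gaps)) {
    warn(sprintf("Sampling gap of %.1f s after row %d.",
                 diff(df$time_s)[gaps[1]], gaps[1]))
  }
  ph_t <- switch(
    dialect,
    ph_total = df$ph,
    ph_nbs = {
      if (is.null(ph_m_tris) || is.null(ph_cal_tris)) {
        abort("NBS dialect needs `ph_m_tris` and `ph_cal_tris`.")
      }
      nbs_to_total(df$ph, ph_m_tris, ph_cal_tris)
    },
    voltage = {
      if (is.null(cal) || is.null(ph_m_tris) || is.null(ph_cal_tris)) {
        abort("Voltage dialect needs `cal`, `ph_m_tris` and `ph_cal_tris`.")
      }
      nbs_to_total(voltage_to_ph(df$voltage_mv, cal), ph_m_tris, ph_cal_tris)
    }
  )
  tibble(
    time_s = df$time_s, ph_t = ph_t,
    o2_signal = df$o2_signal, ar_signal = df$ar_signal,
    light = df$light_umol_m2_s, temp_k = df$temp_c + 273.15
  )
}

#' Write an oscillation trace to CSV
#'
#' Inverse of [read_trace_csv()] for the total-scale pH dialect.
#'
#' @param trace Internal trace tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  readr::write_csv(
    tibble(
      time_s = trace$time_s, ph = trace$ph_t,
      o2_signal = trace$o2_signal, ar_signal = trace$ar_signal,
      light_umol_m2_s = trace$light, temp_c = trace$temp_k - 273.15
    ),
    path
  )
  invisible(path)
}

#' Read a spectrum from CSV
#'
#' @param path CSV with columns `wavelength_nm` and `value`.
#' @return A spectrum tibble (`wavelength`, `value`).
#' @export
read_spectrum_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  if (!all(c("wavelength_nm", "value") %in% names(df))) {
    abort("Spectrum file needs columns `wavelength_nm` and `value`.")
  }
  tibble(wavelength = df$wavelength_nm, value = df$value)
}

#' Read a titration from CSV
#'
#' @param path CSV with columns `acid_amount_g` (or `acid_amount_mL`) and
#'   `ph`.
#' @param sample_mass,acid_conc See [titration_record()].
#' @return A [titration_record()].
#' @export
read_titration_csv <- function(path, sample_mass, acid_conc) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if ("acid_amount_g" %in% names(df)) {
    unit <- "g"; acid <- df$acid_amount_g
  } else if ("acid_amount_mL" %in% names(df)) {
    unit <- "mL"; acid <- df$acid_amount_mL
  } else {
    abort("Titration file needs `acid_amount_g` or `acid_amount_mL`.")
  }
  if (!"ph" %in% names(df)) abort("Titration file needs a `ph` column.")
  titration_record(tibble(acid = acid, ph = df$ph),
                   sample_mass = sample_mass, acid_conc = acid_conc,
                   amount_unit = unit)
}

#' Read a run configuration
#'
#' Loads a YAML run configuration and checks that every referenced file
#' exists. See [run_full_pipeline()] for the recognised keys.
#'
#' @param path YAML file path.
#' @return The configuration as a nested list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(path)
  for (key in c("trace", "absorbance", "lamp", "titration")) {
    p <- cfg$paths[[key]]
    if (!is.null(p)) {
      if (!file.exists(p)) p <- file.path(base, p)
      if (!file.exists(p)) {
        abort(sprintf("Configured file `%s` (%s) does not exist.", key, p))
      }
      cfg$paths[[key]] <- p
    }
  }
  cfg
}

#' Run the full pHOS-MIMS reduction pipeline
#'
#' Orchestrates the end-to-end reduction: load (or accept) a calibrated
#' trace, extract per-segment rates, fit the carbon and (when oxygen data
#' are present) oxygen P-vs-E curves, compute the quantum-yield series when
#' an absorbance spectrum is available, and optionally run the perturbation
#' sensitivity analysis. Every numeric decision (trim, constant set,
#' respiration offsets) is echoed to the run log.
#'
#' @param config A nested list (or path to a YAML file, see
#'   [read_run_config()]) with blocks:
#'   * `paths`: `trace` (CSV; or pass a trace tibble as `trace`),
#'     optionally `absorbance`, `lamp`;
#'   * `medium`: `salinity`, `temperature_c`, `total_alkalinity`, and
#'     optionally `density`, `total_borate`, `total_phosphate`,
#'     `total_silicate`;
#'   * `chla` (ug mL-1), optional `od750`;
#'   * optional `schedule`: `levels`, `duration_s`;
#'   * optional `o2_cal`: `r_sat`, `r_zero`, `salinity`, `temperature_c`;
#'   * optional `trim_s` (default 10), `constants` (default
#'     `"lueker2000"`), `dialect`, `sensitivity` (logical),
#'   * optional `spectrum`: `chla_mg_m3`, `path_m`.
#' @param trace Optional trace tibble overriding `paths$trace`.
#' @return A list of class `phos_run`: `points`, `fit_carbon`,
#'   `fit_oxygen`, `phi`, `sensitivity`, `log`.
#' @export
run_full_pipeline <- function(config, trace = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    inform(msg)
  }
  m <- config$medium
  chem <- medium_chemistry(
    salinity = m$salinity,
    temperature = m$temperature_c + 273.15,
    total_alkalinity = m$total_alkalinity,
    density = m$density %||% 1.0352,
    total_borate = m$total_borate,
    total_phosphate = m$total_phosphate %||% 21.8,
    total_silicate = m$total_silicate %||% 105.6
  )
  constants <- config$constants %||% "lueker2000"
  k <- carb_constants(chem, method = constants)
  say("constants: %s (pK1 %.4f, pK2 %.4f)", constants,
      -log10(k$k1), -log10(k$k2))
  trim_s <- config$trim_s %||% 10
  say("trim_s: %g s per segment", trim_s)
  if (!is.null(config$od750)) {
    ceiling_od <- max_od_for_loss()
    if (config$od750 > ceiling_od) {
      warn(sprintf(
        "od750 = %.2f exceeds the PAR-attenuation ceiling %.2f (>10%% loss: %.1f%%).",
        config$od750, ceiling_od,
        100 * attenuation_fraction(config$od750)
      ))
    }
    say("od750: %.3f (ceiling %.3f)", config$od750, max_od_for_loss())
  }
  if (is.null(trace)) {
    trace <- read_trace_csv(config$paths$trace,
                            dialect = config$dialect %||% "ph_total")
    say("trace: %s (%d samples)", config$paths$trace, nrow(trace))
  }
  o2_cal <- NULL
  if (!is.null(config$o2_cal)) {
    oc <- config$o2_cal
    o2_cal <- oxygen_calibration(oc$r_sat, oc$r_zero,
                                 oc$salinity %||% chem$salinity,
                                 (oc$temperature_c %||%
                                    (chem$temperature - 273.15)) + 273.15)
    say("o2_cal: r_sat %.3f, r_zero %.3f, O2_sat %.1f umol/kg",
        o2_cal$r_sat, o2_cal$r_zero, o2_cal$o2_sat)
  }
  schedule <- NULL
  if (!is.null(config$schedule)) {
    schedule <- light_schedule(config$schedule$levels,
                               config$schedule$duration_s %||% 120)
  }
  pts <- pve_points(trace, chem, config$chla, o2_cal = o2_cal,
                    schedule = schedule, trim_s = trim_s, k = k)
  fit_c <- fit_platt_offset(pts, rate = rate_dic, gas = "carbon")
  say("carbon fit: P_max %.2f, alpha %.3f, beta %.4g, R %.2f",
      fit_c$p_max, fit_c$alpha, fit_c$beta, fit_c$respiration)
  fit_o <- NULL
  if ("rate_o2" %in% names(pts)) {
    fit_o <- fit_platt_offset(pts, rate = rate_o2, gas = "oxygen")
    say("oxygen fit: P_max %.2f, alpha %.3f, beta %.4g, R %.2f",
        fit_o$p_max, fit_o$alpha, fit_o$beta, fit_o$respiration)
  }
  phi <- NULL
  if (!is.null(config$paths$absorbance)) {
    ab <- read_spectrum_csv(config$paths$absorbance)
    sp <- config$spectrum %||% list()
    a_star <- specific_absorption(ab, sp$chla_mg_m3 %||% (config$chla * 1000),
                                  sp$path_m %||% 0.01)
    lamp <- if (!is.null(config$paths$lamp)) {
      read_spectrum_csv(config$paths$lamp)
    } else {
      lamp_spectrum()
    }
    phi <- phi_series(fit_carbon = fit_c, fit_oxygen = fit_o,
                      a_star = a_star, lamp_shape = lamp)
    g <- glance(phi)
    say("phi_max (carbon): %.4f at E = %g", g$phi_max_carbon,
        g$e_at_phi_max_carbon)
  }
  sens <- NULL
  if (isTRUE(config$sensitivity)) {
    sens <- sensitivity_table(trace, chem, config$chla,
                              schedule = schedule, trim_s = trim_s)
    say("sensitivity: %d perturbations", nrow(sens) - 1)
  }
  structure(
    list(points = pts, fit_carbon = fit_c, fit_oxygen = fit_o,
         phi = phi, sensitivity = sens, chem = chem, log = log),
    class = "phos_run"
  )
}

#' @export
print.phos_run <- function(x, ...) {
  cat("<phos_run>\n")
  print(x$fit_carbon)
  if (!is.null(x$fit_oxygen)) print(x$fit_oxygen)
  if (!is.null(x$phi)) print(glance(x$phi))
  invisible(x)
}
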