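# Perturbation sensitivity of the fitted P-vs-E parameters.

#' Default perturbation set
#'
#' The two measurement-error families the method is most exposed to: a
#' uniform offset on every processed total-scale pH sample (calibration
#' drift, +/-0.01) and a fractional error on total alkalinity (titration
#' uncertainty, +/-1 %).
#'
#' @return Tibble with columns `label`, `type` (`"ph_offset"` or
#'   `"at_scale"`) and `value`.
#' @export
default_perturbations <- function() {
  tibble(
    label = c("A_T +1%", "A_T -1%", "pH +0.01", "pH -0.01"),
    type = c("at_scale", "at_scale", "ph_offset", "ph_offset"),
    value = c(0.01, -0.01, 0.01, -0.01)
  )
}

#' Sensitivity of fitted P-vs-E parameters to measurement errors
#'
#' Reprocesses the same trace under each perturbation — offsetting every pH
#' sample or scaling the total alkalinity — and reports the percent change
#' of the fitted `P_max`, `alpha` and `beta` relative to the unperturbed
#' baseline. A uniform pH offset rescales all segment rates almost
#' multiplicatively, so `P_max` and `alpha` move together.
#'
#' @param trace Trace tibble with a total-scale `ph_t` column.
#' @param chem A [medium_chemistry()].
#' @param chla Chlorophyll a, ug mL-1.
#' @param perturbations Tibble as from [default_perturbations()].
#' @param ... Further arguments to [pve_points()] (e.g. `schedule`,
#'   `trim_s`, `o2_cal`).
#' @return A tibble of class `sensitivity_report`: one baseline row (all
#'   deltas 0) plus one row per perturbation with `d_p_max_pct`,
#'   `d_alpha_pct`, `d_beta_pct` for carbon (and oxygen when available).
#' @export
sensitivity_table <- function(trace, chem, chla,
                              perturbations = default_perturbations(),
                              ...) {
  run <- function(tr, ch) {
    pts <- pve_points(tr, ch, chla, ...)
    fits <- list(carbon = fit_platt_offset(pts, rate = rate_dic,
                                           gas = "carbon"))
    if ("rate_o2" %in% names(pts)) {
      fits$oxygen <- fit_platt_offset(pts, rate = rate_o2, gas = "oxygen")
    }
    fits
  }
  base <- run(trace, chem)
  pct <- function(new, old) {
    # a parameter negligible in both runs (e.g. beta fitted ~0) did not move
    if (abs(old) < 1e-3) return(if (abs(new) < 1e-3) 0 else NA_real_)
    100 * (new - old) / old
  }
  one_row <- function(label, fits) {
    row <- tibble(label = label)
    for (nm in names(base)) {
      row[[paste0("d_p_max_pct_", nm)]] <- pct(fits[[nm]]$p_max, base[[nm]]$p_max)
      row[[paste0("d_alpha_pct_", nm)]] <- pct(fits[[nm]]$alpha, base[[nm]]$alpha)
      row[[paste0("d_beta_pct_", nm)]] <- pct(fits[[nm]]$beta, base[[nm]]$beta)
    }
    row
  }
  rows <- list(one_row("baseline", base))
  for (i in seq_len(nrow(perturbations))) {
    p <- perturbations[i, ]
    fits <- switch(
      p$type,
      ph_offset = {
        tr2 <- trace
        tr2$ph_t <- tr2$ph_t + p$value
        tryCatch(run(tr2, chem), error = function(e) {
          abort(sprintf("Perturbation '%s' failed: %s", p$label,
                        conditionMessage(e)))
        })
      },
      at_scale = {
        ch2 <- chem
        ch2$total_alkalinity <- chem$total_alkalinity * (1 + p$value)
        tryCatch(run(trace, ch2), error = function(e) {
          abort(sprintf("Perturbation '%s' failed: %s", p$label,
                        conditionMessage(e)))
        })
      },
      abort(sprintf("Unknown perturbation type '%s'.", p$type))
    )
    rows[[length(rows) + 1]] <- one_row(p$label, fits)
  }
  out <- bind_rows(rows)
  class(out) <- c("sensitivity_report", class(out))
  out
}
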