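# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_rect
#'   geom_errorbar geom_hline labs theme_minimal facet_wrap vars
#' @export
ggplot2::autoplot

#' Plot a P-vs-E fit
#'
#' Measured net rates with the fitted net curve (respiration offset
#' subtracted).
#'
#' @param object A `pve_fit`.
#' @param n_curve Points used to draw the curve.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pve_fit <- function(object, n_curve = 200, ...) {
  grid <- seq(0, max(object$points$light), length.out = n_curve)
  curve <- tibble(light = grid, rate = predict(object, grid, net = TRUE))
  ggplot(object$points, aes(x = light, y = rate)) +
    geom_hline(yintercept = 0, linetype = 3, colour = "grey50") +
    geom_line(data = curve, colour = "steelblue") +
    geom_point() +
    labs(
      x = expression("Irradiance (" * mu * "mol quanta" ~ m^-2 ~ s^-1 * ")"),
      y = expression("Net rate (" * mu * "mol" ~ mg^-1 ~ "Chla" ~ h^-1 * ")"),
      title = sprintf("P vs E (%s): P_max = %.1f, alpha = %.2f",
                      object$gas, object$p_max, object$alpha)
    ) +
    theme_minimal()
}

#' Plot a quantum-yield series
#'
#' Net quantum yield versus irradiance for the gases present, with the
#' peak-yield locations marked.
#'
#' @param object A [phi_series()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phi_series <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              cols = dplyr::starts_with("phi_"),
                              names_to = "gas", names_prefix = "phi_",
                              values_to = "phi")
  peaks <- tibble(
    gas = names(attr(object, "phi_max")),
    phi = unname(attr(object, "phi_max")),
    light = unname(attr(object, "e_at_phi_max"))
  )
  ggplot(long, aes(x = light, y = phi, colour = gas)) +
    geom_line() +
    geom_point(data = peaks, shape = 1, size = 3) +
    labs(
      x = expression("Irradiance (" * mu * "mol quanta" ~ m^-2 ~ s^-1 * ")"),
      y = expression(Phi ~ "(mol per mol quanta absorbed)")
    ) +
    theme_minimal()
}

#' Plot an oscillation trace
#'
#' pH (and, when present, the O2/Ar ratio) against time with the light
#' schedule shaded.
#'
#' @param trace A trace tibble.
#' @return A ggplot.
#' @export
plot_trace <- function(trace) {
  trace <- as_tibble(trace)
  r <- rle(trace$light)
  ends <- cumsum(r$lengths)
  segs <- tibble(
    xmin = trace$time_s[c(1, head(ends, -1) + 1)],
    xmax = trace$time_s[ends],
    light = r$values
  )
  long <- tibble(time_s = trace$time_s, value = trace$ph_t,
                 channel = "pH (total scale)")
  if (all(c("o2_signal", "ar_signal") %in% names(trace))) {
    long <- bind_rows(long, tibble(
      time_s = trace$time_s,
      value = trace$o2_signal / trace$ar_signal,
      channel = "O2/Ar signal ratio"
    ))
  }
  ggplot(long, aes(x = time_s, y = value)) +
    geom_rect(data = segs[segs$light > 0, ],
              aes(xmin = xmin, xmax = xmax, ymin = -Inf, ymax = Inf,
                  alpha = light),
              inherit.aes = FALSE, fill = "gold") +
    ggplot2::scale_alpha_continuous(range = c(0.08, 0.35), guide = "none") +
    geom_line() +
    facet_wrap(vars(channel), ncol = 1, scales = "free_y") +
    labs(x = "Time (s)", y = NULL) +
    theme_minimal()
}
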