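# Oscillation-trace reduction: segmentation, slopes, per-step rates.

#' Default light/dark oscillation schedule
#'
#' The stepped protocol: an initial 2-min dark period (the light = 0 level),
#' then each increasing light step separated by a 2-min dark interval, with
#' a closing dark period.
#'
#' @param levels Light levels, umol quanta m-2 s-1; the leading 0 is the
#'   measured dark level.
#' @param duration_s Segment duration, s.
#' @return A tibble with columns `duration_s` and `light`.
#' @export
#' @examples
#' light_schedule()
light_schedule <- function(levels = c(0, 20, 50, 200, 500, 1000, 2000),
                           duration_s = 120) {
  if (length(levels) < 1) abort("`levels` must be nonempty.")
  steps <- levels[-1]
  light <- c(levels[1], rbind(steps, 0))  # 0, L1, 0, L2, 0, ...
  tibble(duration_s = rep(duration_s, length(light)), light = light)
}

.validate_trace <- function(trace) {
  trace <- as_tibble(trace)
  need <- c("time_s", "light")
  miss <- setdiff(need, names(trace))
  if (length(miss)) {
    abort(paste0("Trace is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(diff(trace$time_s) <= 0)) {
    abort(sprintf("Trace time must be strictly increasing (row %d).",
                  which(diff(trace$time_s) <= 0)[1] + 1))
  }
  trace
}

#' Split a trace into dark/light segments
#'
#' Labels each sample with a segment index and the segment's light level.
#' With a declared `schedule` the segment boundaries follow the schedule and
#' are cross-checked against the transitions of the recorded light channel
#' (mismatch beyond `tol_s` is an error); without one, boundaries are
#' detected from changes in the light channel.
#'
#' @param trace A trace tibble with at least `time_s` and `light` columns.
#' @param schedule Optional schedule tibble (`duration_s`, `light`) as from
#'   [light_schedule()].
#' @param tol_s Allowed disagreement between declared and recorded
#'   transitions, s.
#' @return The trace with added columns `segment` (integer) and
#'   `segment_light`.
#' @export
segment_trace <- function(trace, schedule = NULL, tol_s = 5) {
  trace <- .validate_trace(trace)
  r <- rle(trace$light)
  detected_starts <- trace$time_s[cumsum(c(1, head(r$lengths, -1)))]
  if (is.null(schedule)) {
    trace$segment <- rep(seq_along(r$lengths), r$lengths)
    trace$segment_light <- rep(r$values, r$lengths)
    return(trace)
  }
  schedule <- as_tibble(schedule)
  if (sum(schedule$duration_s) > diff(range(trace$time_s)) + 1) {
    abort("Schedule is longer than the trace.")
  }
  starts <- trace$time_s[1] + cumsum(c(0, head(schedule$duration_s, -1)))
  # compare declared vs recorded transition times (same count => pairwise)
  if (length(detected_starts) == length(starts) &&
      any(abs(detected_starts - starts) > tol_s)) {
    abort(sprintf(
      "Schedule mismatch: declared and recorded light transitions differ by up to %.1f s (> %g s).",
      max(abs(detected_starts - starts)), tol_s
    ))
  }
  ends <- c(starts[-1], starts[length(starts)] +
              schedule$duration_s[nrow(schedule)])
  seg <- findInterval(trace$time_s, starts)
  keep <- seg >= 1 & trace$time_s < ends[length(ends)]
  trace <- trace[keep, , drop = FALSE]
  trace$segment <- seg[keep]
  trace$segment_light <- schedule$light[trace$segment]
  trace
}

#' Least-squares rate of change over a segment
#'
#' Ordinary least squares slope of a concentration series against time
#' after discarding the first `trim_s` seconds (electrode/membrane response
#' transient).
#'
#' @param values Concentration samples.
#' @param time Sample times, s.
#' @param trim_s Seconds to trim from the segment start (default 10).
#' @param min_points Minimum samples after trimming (default 30).
#' @return A one-row tibble: `slope` (per s), `se`, `r_squared`, `n`.
#' @export
#' @examples
#' segment_slope(2000 - 0.05 * 0:119, 0:119)
segment_slope <- function(values, time, trim_s = 10, min_points = 30) {
  keep <- time >= time[1] + trim_s
  if (sum(keep) < min_points) {
    abort(sprintf(
      "Insufficient data: %d points after trimming %g s (need >= %d).",
      sum(keep), trim_s, min_points
    ))
  }
  x <- time[keep]
  y <- values[keep]
  # closed-form OLS: robust to numerically perfect (noise-free) segments
  n <- length(x)
  xc <- x - mean(x)
  yc <- y - mean(y)
  sxx <- sum(xc^2)
  slope <- sum(xc * yc) / sxx
  res <- yc - slope * xc
  rss <- sum(res^2)
  tss <- sum(yc^2)
  tibble(
    slope = slope,
    se = sqrt(rss / (n - 2) / sxx),
    r_squared = if (tss > 0) 1 - rss / tss else 1,
    n = n
  )
}

#' DIC time series from a calibrated pH trace
#'
#' Applies [dic_from_ph()] sample-by-sample at the medium's constant total
#' alkalinity.
#'
#' @param trace Trace tibble with a total-scale `ph_t` column.
#' @param chem A [medium_chemistry()].
#' @param k Optional [carb_constants()].
#' @return The trace with an added `dic` column (umol kg-1).
#' @export
trace_to_dic <- function(trace, chem, k = NULL) {
  trace <- as_tibble(trace)
  if (!"ph_t" %in% names(trace)) abort("Trace needs a `ph_t` column.")
  bad <- which(trace$ph_t < 6 | trace$ph_t > 10)
  if (length(bad)) {
    abort(sprintf("pH outside [6, 10] at sample %d (pH = %.3f).",
                  bad[1], trace$ph_t[bad[1]]))
  }
  k <- k %||% carb_constants(chem)
  trace$dic <- dic_from_ph(trace$ph_t, chem, k)$dic
  trace
}

#' Per-segment photosynthesis rates from a calibrated trace
#'
#' Reduces an oscillation trace to chlorophyll-specific rates per light
#' step: the DIC slope of each segment (umol kg-1 s-1) is converted to
#' volumetric units with the medium density and normalised to Chla and
#' hours; uptake is reported positive. When an oxygen calibration and
#' `o2_signal`/`ar_signal` columns are present, oxygen evolution rates are
#' produced the same way (positive = evolution). The first dark segment
#' supplies the dark-respiration point (`used = TRUE`, light 0); later dark
#' segments are retained for drift QC but flagged `used = FALSE`.
#'
#' @param trace Trace tibble (`time_s`, `ph_t`, `light`, optionally
#'   `o2_signal`, `ar_signal`).
#' @param chem A [medium_chemistry()].
#' @param chla Chlorophyll a concentration, ug mL-1 (= mg L-1; > 0).
#' @param o2_cal Optional [oxygen_calibration()].
#' @param schedule Optional declared schedule for [segment_trace()].
#' @param trim_s,min_points Passed to [segment_slope()].
#' @param k Optional [carb_constants()].
#' @return A tibble of class `pve_points`: one row per segment with
#'   `segment`, `light`, `rate_dic`, `se_dic`, `r2_dic` (and `rate_o2`,
#'   `se_o2`, `r2_o2` when oxygen is available), `n`, `used`.
#' @export
pve_points <- function(trace, chem, chla, o2_cal = NULL, schedule = NULL,
                       trim_s = 10, min_points = 30, k = NULL) {
  if (!is.numeric(chla) || chla <= 0) {
    abort("`chla` must be > 0 (ug/mL); check the run configuration.")
  }
  k <- k %||% carb_constants(chem)
  trace <- segment_trace(trace, schedule)
  trace <- trace_to_dic(trace, chem, k)
  has_o2 <- !is.null(o2_cal) &&
    all(c("o2_signal", "ar_signal") %in% names(trace))
  if (has_o2) {
    trace$o2_conc <- oxygen_from_signal(trace$o2_signal / trace$ar_signal,
                                        o2_cal)
  }
  segs <- split(trace, trace$segment)
  if (segs[[1]]$segment_light[1] != 0) {
    abort("Protocol error: the trace must start with a dark segment (light 0).")
  }
  to_rate <- function(slope) slope * chem$density * 3600 / chla
  rows <- purrr::imap(segs, function(sg, id) {
    sl_d <- segment_slope(sg$dic, sg$time_s, trim_s, min_points)
    out <- tibble(
      segment = as.integer(id),
      light = sg$segment_light[1],
      rate_dic = -to_rate(sl_d$slope),
      se_dic = to_rate(sl_d$se),
      r2_dic = sl_d$r_squared,
      n = sl_d$n
    )
    if (has_o2) {
      sl_o <- segment_slope(sg$o2_conc, sg$time_s, trim_s, min_points)
      out$rate_o2 <- to_rate(sl_o$slope)
      out$se_o2 <- to_rate(sl_o$se)
      out$r2_o2 <- sl_o$r_squared
    }
    out
  })
  out <- bind_rows(rows)
  out <- out[order(out$segment), ]
  first_dark <- which(out$light == 0)[1]
  out$used <- out$light > 0
  out$used[first_dark] <- TRUE
  class(out) <- c("pve_points", class(out))
  out
}
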