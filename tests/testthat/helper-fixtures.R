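# Shared fixtures: a reference medium and constants, plus small builders.

ref_chem <- function(...) asw_medium(...)

ref_constants <- function(chem = ref_chem()) carb_constants(chem)

# trace with an exactly linear DIC course per segment (built through the
# inverse carbonate solve, so trace_to_dic must recover the input exactly)
linear_dic_trace <- function(chem, slopes, duration_s = 120,
                             lights = NULL, dic0 = NULL, k = NULL) {
  k <- k %||% carb_constants(chem)
  dic0 <- dic0 %||% dic_from_ph(8.05, chem, k)$dic
  lights <- lights %||% c(0, rep(200, length(slopes) - 1))
  dic <- dic0
  out <- list()
  t0 <- 0
  for (i in seq_along(slopes)) {
    tt <- seq_len(duration_s) - 1
    seg_dic <- dic + slopes[i] * tt
    out[[i]] <- tibble::tibble(
      time_s = t0 + tt,
      ph_t = ph_from_dic(seg_dic, chem, k),
      light = lights[i]
    )
    dic <- seg_dic[duration_s] + slopes[i]
    t0 <- t0 + duration_s
  }
  dplyr::bind_rows(out)
}

`%||%` <- rlang::`%||%`
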