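#' Peak and area of a voltage response
#'
#' Baseline is the mean voltage in `baseline_window`; peak is the maximum of
#' `v - baseline` within `response_window` (mV) and area the trapezoidal
#' integral of `v - baseline` over the window (mV ms), negative excursions
#' included. Default windows: baseline the 50 ms preceding the response
#' window; response window 300 ms from stimulus onset (three NMDA decay time
#' constants plus the burst).
#'
#' @param trace tibble with `time` (ms) and `v` (mV) (see [get_trace()]).
#' @param baseline_window,response_window `c(from, to)` in ms.
#' @return list with `peak` (mV), `area` (mV ms), `baseline` (mV).
#' @export
peak_and_area <- function(trace, baseline_window, response_window) {
  if (response_window[2] <= response_window[1] ||
      baseline_window[2] <= baseline_window[1]) {
    abort("windows must be non-empty ascending intervals",
          class = "pir_argument_error")
  }
  if (baseline_window[1] > response_window[1]) {
    abort("baseline window must precede the response window",
          class = "pir_argument_error")
  }
  bsel <- trace$time >= baseline_window[1] & trace$time <= baseline_window[2]
  rsel <- trace$time >= response_window[1] & trace$time <= response_window[2]
  if (!any(bsel) || !any(rsel)) {
    abort("window contains no samples", class = "pir_argument_error")
  }
  base <- mean(trace$v[bsel])
  dv <- trace$v[rsel] - base
  tt <- trace$time[rsel]
  list(peak = max(dv), area = trapz_int(tt, dv), baseline = base)
}

trapz_int <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Subtract a matched background-only trace
#'
#' Pointwise difference of two traces on an identical time base (trials are
#' matched by seed so the background realisation is shared).
#'
#' @param trace,background tibbles with `time` and `v`.
#' @return tibble with `time` and `v` (the difference).
#' @export
background_subtract <- function(trace, background) {
  if (nrow(trace) != nrow(background) ||
      max(abs(trace$time - background$time)) > 1e-9) {
    abort("time bases differ", class = "pir_argument_error")
  }
  tibble(time = trace$time, v = trace$v - background$v)
}

#' Pairing nonlinearity ratio
#'
#' The ratio between the area under the curve of the background-subtracted
#' response to the paired stimulus and the area under the expected linear
#' summation of the two single responses, over the response window. A value
#' of 1 indicates a linear system; larger/smaller values indicate supra-/
#' sub-linear summation. Trials whose expected-linear area is near zero or
#' negative yield `NA` (undefined ratio, to be excluded and counted rather
#' than clipped, avoiding infinite-ratio artifacts).
#'
#' @param actual_pair,single_1,single_2,background traces (tibbles with
#'   `time`, `v`) from trials sharing the same background realisation.
#' @param window `c(from, to)` response window, ms.
#' @param min_expected_auc smallest expected-linear area (mV ms) for which
#'   the ratio is considered defined.
#' @return the ratio (or `NA` if undefined).
#' @export
pairing_nonlinearity <- function(actual_pair, single_1, single_2, background,
                                 window, min_expected_auc = 0) {
  pairdiff <- background_subtract(actual_pair, background)
  s1 <- background_subtract(single_1, background)
  s2 <- background_subtract(single_2, background)
  sel <- pairdiff$time >= window[1] & pairdiff$time <= window[2]
  tt <- pairdiff$time[sel]
  auc_pair <- trapz_int(tt, pairdiff$v[sel])
  auc_lin <- trapz_int(tt, s1$v[sel] + s2$v[sel])
  if (auc_lin <= max(0, min_expected_auc)) return(NA_real_)
  auc_pair / auc_lin
}

#' Percent threshold reduction in a paired condition
#'
#' `100 * (theta_unpaired - theta_paired) / theta_unpaired`.
#'
#' @param theta_unpaired,theta_paired spike thresholds (same units).
#' @export
threshold_reduction <- function(theta_unpaired, theta_paired) {
  if (!is.finite(theta_unpaired) || theta_unpaired <= 0) {
    abort("unpaired threshold must be positive", class = "pir_argument_error")
  }
  100 * (theta_unpaired - theta_paired) / theta_unpaired
}
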