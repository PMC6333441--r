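#' @export
print.pir_io_curve <- function(x, ...) {
  cat("<pir_io_curve> ", nrow(x$summary), " intensities x ",
      max(x$trials$trial), " trial(s)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Tidy an input-output curve
#'
#' @param x a `pir_io_curve`.
#' @param ... unused.
#' @return per-intensity summary tibble (means and SDs of somatic and
#'   dendritic peak and area).
#' @export
tidy.pir_io_curve <- function(x, ...) x$summary

#' @export
glance.pir_io_curve <- function(x, ...) {
  th <- detect_threshold(x)
  tibble(n_intensities = nrow(x$summary),
         trials = max(x$trials$trial),
         spike_detected = th$detected,
         threshold_intensity = th$threshold_intensity,
         threshold_voltage = th$threshold_voltage)
}

#' Plot an input-output curve
#'
#' @param object a `pir_io_curve`.
#' @param measure `"soma"` or `"dend"`.
#' @param ... unused.
#' @export
autoplot.pir_io_curve <- function(object, measure = c("soma", "dend"), ...) {
  measure <- match.arg(measure)
  col <- paste0("peak_", measure, "_mean")
  sdc <- paste0("peak_", measure, "_sd")
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$intensity, y = .data[[col]])) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data[[col]] - .data[[sdc]],
      ymax = .data[[col]] + .data[[sdc]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "intensity (synapses)",
                  y = sprintf("peak %s response (mV)", measure))
}

#' @export
print.pir_pairing <- function(x, ...) {
  cat("<pir_pairing> relation: ", x$relation,
      ", bias EPSP ", sprintf("%.2f", x$bias_epsp), " mV",
      ", threshold reduction ",
      if (is.na(x$reduction_pct)) "NA" else sprintf("%.1f%%", x$reduction_pct),
      "\n", sep = "")
  invisible(x)
}

#' Tidy a pairing experiment
#'
#' @param x a `pir_pairing`.
#' @param ... unused.
#' @return long tibble: per-intensity summaries for the unpaired and paired
#'   conditions.
#' @export
tidy.pir_pairing <- function(x, ...) {
  bind_rows(mutate(x$unpaired$summary, condition = "unpaired"),
            mutate(x$paired$summary, condition = "paired"))
}

#' @export
glance.pir_pairing <- function(x, ...) {
  tibble(relation = x$relation,
         bias_epsp = x$bias_epsp,
         time_shift = x$time_shift,
         threshold_unpaired = x$threshold_unpaired$threshold_intensity,
         threshold_paired = x$threshold_paired$threshold_intensity,
         reduction_pct = x$reduction_pct)
}

#' Plot a pairing experiment (unpaired vs paired input-output curves)
#'
#' @param object a `pir_pairing`.
#' @param ... unused.
#' @export
autoplot.pir_pairing <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$intensity, y = .data$peak_soma_mean,
                                   colour = .data$condition)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "driver intensity (synapses)", y = "peak somatic EPSP (mV)",
                  colour = NULL)
}

#' @export
print.pir_cvd <- function(x, ...) {
  cat("<pir_cvd> clustering fraction ", x$clustering_fraction,
      if (x$ohmic) " (Ohmic NMDA)", ": mean peak ",
      sprintf("%.2f", mean(x$trials$peak)), " mV over ", nrow(x$trials),
      " trial(s)\n", sep = "")
  invisible(x)
}

#' @export
tidy.pir_cvd <- function(x, ...) x$trials

#' @export
glance.pir_cvd <- function(x, ...) {
  tibble(clustering_fraction = x$clustering_fraction, ohmic = x$ohmic,
         trials = nrow(x$trials),
         mean_peak = mean(x$trials$peak), sd_peak = sd(x$trials$peak),
         mean_area = mean(x$trials$area))
}

#' Plot clustered-vs-dispersed trial distributions
#'
#' @param object a `pir_cvd` (or a list of them, e.g. several clustering
#'   fractions).
#' @param ... further `pir_cvd` objects to overlay.
#' @export
autoplot.pir_cvd <- function(object, ...) {
  objs <- c(list(object), Filter(function(o) inherits(o, "pir_cvd"), list(...)))
  df <- bind_rows(lapply(objs, function(o) {
    mutate(o$trials, clustering = factor(o$clustering_fraction),
           ohmic = o$ohmic)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$clustering, y = .data$peak)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "clustering fraction",
                  y = "peak somatic EPSP above background (mV)")
}

#' @export
print.pir_glom <- function(x, ...) {
  cat("<pir_glom> ", nrow(x$trials), " trial(s); mean ratios:",
      paste(vapply(x$pairs, function(p) {
        nm <- paste0("ratio_", paste(p, collapse = ""))
        sprintf(" %s %.2f", paste(p, collapse = ""),
                mean(x$trials[[nm]], na.rm = TRUE))
      }, character(1)), collapse = ","), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.pir_glom <- function(x, ...) x$trials

#' @export
glance.pir_glom <- function(x, ...) {
  out <- tibble(trials = nrow(x$trials))
  for (p in x$pairs) {
    nm <- paste(p, collapse = "")
    r <- x$trials[[paste0("ratio_", nm)]]
    out[[paste0("mean_ratio_", nm)]] <- mean(r, na.rm = TRUE)
    out[[paste0("undefined_", nm)]] <- sum(is.na(r))
  }
  out
}

#' Plot pairing-nonlinearity distributions per glomerular combination
#'
#' @param object a `pir_glom`.
#' @param ... unused.
#' @export
autoplot.pir_glom <- function(object, ...) {
  df <- bind_rows(lapply(object$pairs, function(p) {
    nm <- paste(p, collapse = "")
    tibble(pair = nm, ratio = object$trials[[paste0("ratio_", nm)]])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = .data$ratio)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "glomerular combination", y = "pairing nonlinearity")
}

#' Plot a simulated voltage trace
#'
#' @param object a `pir_sim`.
#' @param ... unused.
#' @export
autoplot.pir_sim <- function(object, ...) {
  df <- bind_rows(lapply(seq_len(ncol(object$v)), function(j) {
    tibble(time = object$time, v = object$v[, j],
           site = colnames(object$v)[j])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$v,
                                   colour = .data$site)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)", colour = NULL)
}
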