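#' Default run configuration
#'
#' Nested configuration mirroring the model blocks: morphology (generator
#' parameters or an SWC path), biophysics, synapses, and protocol settings.
#' All defaults equal the model's published parameter values.
#'
#' @return a named list.
#' @export
default_run_config <- function() {
  list(
    morphology = list(
      swc = NULL,
      generator = morph_params(),
      max_seg_len = 4.6
    ),
    biophysics = list(
      Rm = 25000, Ra = 100, Cm = 1, E_rest = -70,
      channels = "none",  # "none", "soma" or "all"
      gNa = 1000, ENa = 50, gKdr = 500, gKs = 20, EK = -87
    ),
    synapses = list(
      unitary_meaning = "event_mean", gaba_meaning = "event_mean",
      n_slots = 5, pr = 0.1, replenish_rate = 100,
      lot_band_start = 250
    ),
    protocol = list(
      dt = 0.025, trials = 20, duration = 600,
      ohmic_nmda = FALSE, scale = 1,
      intensities = c(0, 1, 2, 3, 4, 6, 8, 10, 12),
      site_distance = 280, bias_distance = 280,
      bias_intensity = 3, time_shift = 0,
      n_signal_exc = 20, n_signal_inh = 40, clustering_fraction = 1
    ),
    seed = 1
  )
}

required_config_keys <- function() {
  list(morphology = c("max_seg_len"),
       biophysics = c("Rm", "Ra", "Cm", "E_rest"),
       synapses = c("unitary_meaning", "n_slots", "pr", "replenish_rate"),
       protocol = c("dt", "trials", "duration"))
}

#' Validate a run configuration
#'
#' Checks that the required blocks and keys are present and of the right
#' type; the error message lists every offending key.
#'
#' @param config a configuration list.
#' @return `config`, invisibly.
#' @export
validate_config <- function(config) {
  req <- required_config_keys()
  missing <- character(0)
  for (block in names(req)) {
    if (is.null(config[[block]])) {
      missing <- c(missing, block)
      next
    }
    for (key in req[[block]]) {
      if (is.null(config[[block]][[key]])) {
        missing <- c(missing, paste0(block, ".", key))
      }
    }
  }
  if (length(missing) > 0) {
    abort(paste0("config error: missing key(s): ",
                 paste(missing, collapse = ", ")),
          class = "pir_config_error")
  }
  num_keys <- c("biophysics.Rm", "biophysics.Ra", "biophysics.Cm",
                "protocol.dt", "protocol.duration")
  for (nk in num_keys) {
    parts <- strsplit(nk, ".", fixed = TRUE)[[1]]
    v <- config[[parts[1]]][[parts[2]]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort(paste0("config error: key ", nk, " must be a positive number"),
            class = "pir_config_error")
    }
  }
  invisible(config)
}

#' Read a run configuration from YAML
#'
#' Missing keys fall back to [default_run_config()]; the merged
#' configuration is validated.
#'
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  config <- modifyList(default_run_config(), user)
  validate_config(config)
  config
}

build_system_from_config <- function(config, seed = NULL) {
  seed <- seed %||% config$seed
  morph <- if (!is.null(config$morphology$swc)) {
    read_swc(config$morphology$swc)
  } else {
    gp <- config$morphology$generator %||% morph_params()
    if (!all(c("n_primary", "length_means") %in% names(gp))) {
      gp <- do.call(morph_params, gp)
    }
    generate_synthetic_morphology(gp, seed = seed)
  }
  bio <- config$biophysics
  passive <- passive_params(bio$Rm, bio$Ra, bio$Cm, bio$E_rest)
  grid <- discretize(morph, config$morphology$max_seg_len, passive)
  channels <- if (!identical(bio$channels, "none") && !is.null(bio$channels)) {
    channel_set(gNa = bio$gNa, ENa = bio$ENa, gKdr = bio$gKdr, gKs = bio$gKs,
                EK = bio$EK, placement = bio$channels)
  } else NULL
  compartmental_system(grid, passive, channels = channels,
                       unitary_meaning = config$synapses$unitary_meaning,
                       gaba_meaning = config$synapses$gaba_meaning %||% "event_mean",
                       ohmic_nmda = isTRUE(config$protocol$ohmic_nmda))
}

lot_site_from_config <- function(system, config) {
  cc <- system$grid$comps
  d <- config$protocol$site_distance %||% 280
  i <- which.min(abs(cc$path_dist - d))
  dendritic_location(cc$section[i], (cc$arc0[i] + cc$arc1[i]) / 2)
}

#' Run a simulation protocol from a configuration
#'
#' Dispatches one of the pipeline subcommands, writes tidy CSV and a JSON
#' summary (stamped with the seed and a configuration hash) into `out_dir`,
#' and returns the result object invisibly.
#'
#' Subcommands: `generate-morphology` (writes SWC + summary),
#' `calibrate` (unitary-input calibration), `io-curve`,
#' `pairing`, `clustered-dispersed`, `glomerular`, and `background-check`
#' (mean background depolarization across trials).
#'
#' @param config configuration list (see [read_run_config()]).
#' @param subcommand one of the protocol names above.
#' @param seed overrides `config$seed`.
#' @param out_dir output directory (created if needed); `NULL` writes
#'   nothing.
#' @export
run_protocol <- function(config, subcommand, seed = NULL, out_dir = NULL) {
  validate_config(config)
  seed <- seed %||% config$seed
  pc <- config$protocol
  hash <- rlang::hash(config)

  emit <- function(name, tbl, summary) {
    if (is.null(out_dir)) return(invisible(NULL))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    summary$seed <- seed
    summary$config_hash <- hash
    if (!is.null(tbl)) {
      tbl$seed <- seed
      tbl$config_hash <- hash
      readr::write_csv(tbl, file.path(out_dir, paste0(name, ".csv")))
    }
    jsonlite::write_json(summary, file.path(out_dir, paste0(name, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  if (subcommand == "generate-morphology") {
    gp <- config$morphology$generator %||% morph_params()
    if (!all(c("n_primary", "length_means") %in% names(gp))) {
      gp <- do.call(morph_params, gp)
    }
    morph <- generate_synthetic_morphology(gp, seed = seed)
    grid <- discretize(morph, config$morphology$max_seg_len)
    summ <- morphology_summary(morph, grid)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_swc(morph, file.path(out_dir, "morphology.swc"))
    }
    emit("morphology", morph$sections, summ)
    return(invisible(list(morphology = morph, summary = summ)))
  }

  system <- build_system_from_config(config, seed)

  res <- switch(
    subcommand,
    "background-check" = {
      out <- background_depolarization(system, trials = pc$trials,
                                       duration = pc$duration, dt = pc$dt,
                                       seed = seed)
      emit("background_check", out$trials,
           list(mean_depolarization_mv = out$mean,
                sd_depolarization_mv = out$sd, trials = nrow(out$trials)))
      out
    },
    "calibrate" = {
      site <- lot_site_from_config(system, config)
      cal <- calibrate_unitary_input(system, site, seed = seed, dt = pc$dt)
      emit("calibration", NULL,
           list(scale = cal$scale, mean_epsc_pa = cal$mean_epsc,
                mean_epsp_mv = cal$mean_epsp, trials = cal$trials))
      cal
    },
    "io-curve" = {
      site <- stimulus_site(lot_site_from_config(system, config),
                            scale = pc$scale)
      crv <- io_curve(system, site, pc$intensities, trials = pc$trials,
                      seed = seed, dt = pc$dt)
      th <- detect_threshold(crv)
      emit("io_curve", crv$trials,
           list(threshold_intensity = th$threshold_intensity,
                threshold_voltage = th$threshold_voltage,
                detected = th$detected))
      crv
    },
    "pairing" = {
      driver <- stimulus_site(lot_site_from_config(system, config),
                              scale = pc$scale)
      cc <- system$grid$comps
      bi <- which.min(abs(cc$path_dist - (pc$bias_distance %||% 280)))
      bias <- stimulus_site(dendritic_location(cc$section[bi],
                                               (cc$arc0[bi] + cc$arc1[bi]) / 2),
                            n_synapses = pc$bias_intensity, scale = pc$scale)
      pr <- pairing_experiment(system, driver, bias,
                               time_shift = pc$time_shift %||% 0,
                               intensities = pc$intensities,
                               trials = max(1, pc$trials %/% 10),
                               seed = seed, dt = pc$dt)
      emit("pairing", bind_rows(mutate(pr$unpaired$trials, condition = "unpaired"),
                                mutate(pr$paired$trials, condition = "paired")),
           list(threshold_reduction_pct = pr$reduction_pct,
                relation = pr$relation, bias_epsp_mv = pr$bias_epsp))
      pr
    },
    "clustered-dispersed" = {
      cvd <- clustered_vs_dispersed(system, n_signal_exc = pc$n_signal_exc,
                                    n_signal_inh = pc$n_signal_inh,
                                    clustering_fraction = pc$clustering_fraction,
                                    ohmic = isTRUE(pc$ohmic_nmda),
                                    trials = pc$trials, seed = seed,
                                    scale = pc$scale, dt = pc$dt)
      emit("clustered_dispersed", cvd$trials,
           list(mean_peak_mv = mean(cvd$trials$peak),
                clustering_fraction = pc$clustering_fraction,
                ohmic = isTRUE(pc$ohmic_nmda)))
      cvd
    },
    "glomerular" = {
      gl <- glomerular_combination(system, trials = pc$trials, seed = seed,
                                   scale = pc$scale, dt = pc$dt)
      emit("glomerular", gl$trials,
           list(mean_ratio_AB = mean(gl$trials$ratio_AB, na.rm = TRUE),
                mean_ratio_AC = mean(gl$trials$ratio_AC, na.rm = TRUE),
                undefined_AB = sum(is.na(gl$trials$ratio_AB)),
                undefined_AC = sum(is.na(gl$trials$ratio_AC))))
      gl
    },
    abort(paste0("unknown subcommand: ", subcommand), class = "pir_config_error")
  )
  invisible(res)
}

#' Mean background-driven depolarization
#'
#' Runs `trials` independent realisations of the background population
#' (default 100 AMPA-only excitatory and 20 inhibitory inputs at 10 Hz) and
#' measures the mean somatic depolarization above rest over the steady
#' window (after three membrane time constants).
#'
#' @param system a `pir_system`.
#' @param trials,duration,dt run parameters (ms).
#' @param seed integer seed.
#' @param n_exc,n_inh,rate background population parameters.
#' @param settle time discarded at the start of each trial, ms.
#' @return list with `mean`, `sd` (mV) and the per-trial tibble.
#' @export
background_depolarization <- function(system, trials = 20, duration = 600,
                                      dt = 0.025, seed = 1, n_exc = 100,
                                      n_inh = 20, rate = 10, settle = 150) {
  seeds <- derive_seeds(seed, trials)
  depol <- vapply(seeds, function(s) {
    bg <- generate_background(system$grid, n_exc, n_inh, rate, duration,
                              seed = s)
    sys <- set_synapses(system, bg$synapses, bg$trains)
    sim <- run_simulation(sys, duration, dt = dt, seed = s)
    tr <- get_trace(sim, 1)
    mean(tr$v[tr$time >= settle]) - system$passive$E_rest
  }, numeric(1))
  list(mean = mean(depol), sd = sd(depol),
       trials = tibble(trial = seq_len(trials), depolarization = depol))
}
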