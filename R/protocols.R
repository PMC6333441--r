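#' A focal stimulation site
#'
#' A dendritic location together with the stimulus it delivers: a number of
#' co-activated synapses, each driven by the same presynaptic burst
#' (default 3 pulses at 50 Hz, the focal-stimulation protocol), with an
#' intensity scale multiplying the unitary conductances.
#'
#' @param location a [dendritic_location()].
#' @param n_synapses synapses co-activated at the site.
#' @param pulses,pulse_hz burst structure.
#' @param scale conductance scale (from [calibrate_unitary_input()]).
#' @param footprint_um spatial extent of the activated synapse cluster along
#'   the dendrite (the focal electrode/uncaging footprint), um.
#' @export
stimulus_site <- function(location, n_synapses = 1, pulses = 3, pulse_hz = 50,
                          scale = 1, footprint_um = 30) {
  stopifnot(scale >= 0, n_synapses >= 0, footprint_um > 0)
  structure(list(location = location, n_synapses = n_synapses,
                 pulses = pulses, pulse_hz = pulse_hz, scale = scale,
                 footprint_um = footprint_um),
            class = "pir_stimulus_site")
}

burst_times <- function(onset, pulses, pulse_hz) {
  onset + (seq_len(pulses) - 1) * 1000 / pulse_hz
}

# deterministic, prefix-uniform arc positions along a section (golden-ratio
# sequence): activating the first k of n synapses still covers the window
site_arcs <- function(n, lo = 0.1, hi = 0.95) {
  phi <- (sqrt(5) - 1) / 2
  lo + ((seq_len(n) * phi) %% 1) * (hi - lo)
}

# synapses activated by a focal stimulus: spread within the electrode
# footprint around the site's arc position
site_synapses <- function(site, n, scale, prefix, grid) {
  sec_len <- grid$morph$sections$length[
    match(site$location$section, grid$morph$sections$section)]
  half <- (site$footprint_um %||% 30) / 2 / sec_len
  lo <- max(0.02, site$location$arc - half)
  hi <- min(0.98, site$location$arc + half)
  arcs <- site_arcs(n, lo, hi)
  locs <- lapply(arcs, function(a) dendritic_location(site$location$section, a))
  synapse_population(locs, type = "exc", scale = scale, input_prefix = prefix)
}

derive_seeds <- function(seed, n) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sample.int(2147483646L, n)
}

#' Select driver and bias sites for a pairing experiment
#'
#' The driver sits distally (arc 0.7) on the deepest terminal branch. The
#' bias site is placed by pathway and branch relation: LOT biases sit
#' distally on a terminal branch (the driver's own for `"same"`, the
#' deepest terminal sharing / not sharing the driver's primary dendrite for
#' `"sister"` / `"different"`); IC biases sit at the dendritic location
#' closest to `ic_distance` (default 240 um, the deep end of the
#' intracortical band, giving a driver-bias separation comparable to the
#' ~140-160 um used in the focal LOT-IC pairing recordings) on the driver's
#' own path, on another subtree of the same primary, or under a different
#' primary.
#'
#' @param grid a `pir_grid`.
#' @param relation `"same"`, `"sister"`, or `"different"`.
#' @param pathway `"LOT"` or `"IC"` placement of the bias.
#' @param ic_distance target path distance for IC biases, um.
#' @return list with `driver` and `bias` [dendritic_location()]s.
#' @export
select_pairing_sites <- function(grid, relation = c("same", "sister", "different"),
                                 pathway = c("LOT", "IC"), ic_distance = 240) {
  relation <- match.arg(relation)
  pathway <- match.arg(pathway)
  morph <- grid$morph
  sec <- morph$sections
  term <- terminal_sections(morph)
  tipd <- section_tip_distances(morph)
  tips <- tipd$tip_dist[match(term, tipd$section)]
  drv_sec <- term[which.max(tips)]
  driver <- dendritic_location(drv_sec, 0.7)
  drv_root <- sec$root_id[match(drv_sec, sec$section)]
  drv_path <- section_path_to_root(morph, drv_sec)

  pick_terminal <- function(same_root) {
    ok <- if (same_root) {
      sec$root_id[match(term, sec$section)] == drv_root & term != drv_sec
    } else {
      sec$root_id[match(term, sec$section)] != drv_root
    }
    cand <- term[ok]
    # prefer the most separated branch (fewest shared ancestors with the
    # driver), then the deepest tip
    shared <- vapply(cand, function(s) {
      length(intersect(section_path_to_root(morph, s), drv_path))
    }, numeric(1))
    cand <- cand[shared == min(shared)]
    cand[which.max(tips[match(cand, term)])]
  }
  pick_ic <- function(sections) {
    cc <- grid$comps[grid$comps$section %in% sections, ]
    i <- which.min(abs(cc$path_dist - ic_distance))
    dendritic_location(cc$section[i], (cc$arc0[i] + cc$arc1[i]) / 2)
  }

  bias <- if (pathway == "LOT") {
    switch(relation,
           same = dendritic_location(drv_sec, 0.3),
           sister = dendritic_location(pick_terminal(TRUE), 0.7),
           different = dendritic_location(pick_terminal(FALSE), 0.7))
  } else {
    dend <- sec$section[!sec$is_soma]
    switch(relation,
           same = pick_ic(intersect(drv_path, dend)),
           sister = pick_ic(setdiff(
             dend[sec$root_id[match(dend, sec$section)] == drv_root], drv_path)),
           different = pick_ic(
             dend[sec$root_id[match(dend, sec$section)] != drv_root]))
  }
  list(driver = driver, bias = bias)
}

#' Calibrate the intensity of a single presynaptic input
#'
#' Places one excitatory synapse (AMPA + NMDA) at a distal LOT-zone site and
#' adjusts its conductance scale so that the mean peak somatic voltage-clamp
#' EPSC over `trials` single-spike release trials matches `target_epsc`
#' (default 30 pA) within `tol`. The mean current-clamp somatic EPSP of the
#' calibrated input is reported alongside. Trial means include release
#' failures (the pool releases nothing on ~59% of single spikes).
#'
#' @param system a `pir_system` (its synapses are replaced).
#' @param site a [dendritic_location()] in the LOT zone.
#' @param target_epsc target mean peak EPSC magnitude, pA.
#' @param tol relative tolerance on the target.
#' @param trials release trials per estimate.
#' @param seed integer seed.
#' @param dt integration step, ms.
#' @param scale_bounds admissible scale range; leaving it is a calibration
#'   error.
#' @return list with `scale`, `mean_epsc` (pA), `mean_epsp` (mV), `trials`.
#' @export
calibrate_unitary_input <- function(system, site, target_epsc = 30, tol = 0.1,
                                    trials = 100, seed = 1, dt = 0.025,
                                    scale_bounds = c(1e-3, 1e3)) {
  if (classify_zone(system$grid, site) != "LOT") {
    abort("calibration site must lie in the LOT zone", class = "pir_protocol_error")
  }
  if (scale_bounds[2] <= 0) {
    abort("calibration error: zero-conductance scale bound",
          class = "pir_calibration_error")
  }
  spike_t <- 20
  duration <- 140
  trial_seeds <- derive_seeds(seed, trials)
  syn0 <- synapse_population(list(site), type = "exc", input_prefix = "cal")

  mean_epsc <- function(scale) {
    syn <- syn0
    syn$scale <- scale
    sys <- set_synapses(system, syn, list(cal_1 = spike_t))
    peaks <- vapply(trial_seeds, function(s) {
      sim <- run_simulation(sys, duration, dt = dt, seed = s,
                            clamp = list(site = "soma", hold = system$passive$E_rest))
      base <- mean(sim$i_clamp[sim$time <= spike_t - 2])
      max(base - sim$i_clamp) * 1000 # inward current magnitude, pA
    }, numeric(1))
    mean(peaks)
  }

  scale <- 1
  for (it in 1:8) {
    m <- mean_epsc(scale)
    if (m <= 0) {
      abort("calibration error: no synaptic current at any release",
            class = "pir_calibration_error")
    }
    if (abs(m - target_epsc) / target_epsc <= tol) break
    scale <- scale * target_epsc / m
    if (scale < scale_bounds[1] || scale > scale_bounds[2]) {
      abort("calibration error: target unreachable within scale bounds",
            class = "pir_calibration_error")
    }
  }
  m <- mean_epsc(scale)
  if (abs(m - target_epsc) / target_epsc > tol) {
    abort("calibration error: did not converge to the target EPSC",
          class = "pir_calibration_error")
  }

  syn <- syn0
  syn$scale <- scale
  sys <- set_synapses(system, syn, list(cal_1 = spike_t))
  epsps <- vapply(trial_seeds, function(s) {
    sim <- run_simulation(sys, duration, dt = dt, seed = s)
    tr <- get_trace(sim, 1)
    peak_and_area(tr, c(0, spike_t - 2), c(spike_t, duration))$peak
  }, numeric(1))

  list(scale = scale, mean_epsc = m, mean_epsp = mean(epsps), trials = trials)
}

#' Input-output curve of a stimulation site
#'
#' For each intensity (number of co-activated calibrated synapses at the
#' site) runs `trials` release trials of the burst stimulus and measures the
#' somatic and local dendritic response peak (mV) and area (mV ms) above
#' baseline. With regenerative NMDA conductances the curve is sigmoidal
#' (all-or-none local spike beyond threshold); with Ohmic NMDA it is
#' approximately linear.
#'
#' @param system a `pir_system` (stimulus synapses are added to it).
#' @param site a [stimulus_site()]; its `n_synapses` is overridden by each
#'   intensity.
#' @param intensities ascending integer vector (>= 4 values) of synapse
#'   counts.
#' @param trials trials per intensity.
#' @param seed integer seed.
#' @param dt integration step, ms.
#' @param onset burst onset, ms.
#' @param response_ms response window length, ms.
#' @param extra_synapses,extra_trains additional fixed inputs (used by
#'   [pairing_experiment()] for the bias input).
#' @param deterministic_release see [run_simulation()].
#' @return a `pir_io_curve`: list with `summary` (per-intensity means/SDs),
#'   `trials` (per-trial measurements) and metadata.
#' @export
io_curve <- function(system, site, intensities, trials = 3, seed = 1,
                     dt = 0.025, onset = 50, response_ms = 300,
                     extra_synapses = NULL, extra_trains = NULL,
                     deterministic_release = FALSE) {
  if (length(intensities) < 4) {
    abort("need at least 4 intensities", class = "pir_argument_error")
  }
  if (is.unsorted(intensities)) {
    abort("intensities must be ascending", class = "pir_argument_error")
  }
  duration <- onset + response_ms
  nmax <- max(intensities)
  syn_all <- if (nmax > 0) site_synapses(site, nmax, site$scale, "drv",
                                         system$grid) else NULL
  bt <- burst_times(onset, site$pulses, site$pulse_hz)
  dend_comp <- resolve_comp(system$grid, site$location)
  seeds <- matrix(derive_seeds(seed, length(intensities) * trials),
                  nrow = length(intensities))

  rows <- list()
  for (ii in seq_along(intensities)) {
    k <- intensities[ii]
    syn <- NULL
    trains <- list()
    if (k > 0) {
      syn <- syn_all[syn_all$input_id %in% paste0("drv_", seq_len(k)), ]
      trains <- setNames(rep(list(bt), k), paste0("drv_", seq_len(k)))
    }
    if (!is.null(extra_synapses)) {
      syn <- bind_rows(syn, extra_synapses)
      trains <- c(trains, extra_trains)
    }
    sys <- set_synapses(system, syn, trains)
    for (tr in seq_len(trials)) {
      sim <- run_simulation(sys, duration, dt = dt, seed = seeds[ii, tr],
                            record = list("soma", dend_comp),
                            deterministic_release = deterministic_release)
      pa_s <- peak_and_area(get_trace(sim, 1), c(0, onset - 2), c(onset, duration))
      pa_d <- peak_and_area(get_trace(sim, 2), c(0, onset - 2), c(onset, duration))
      rows[[length(rows) + 1L]] <- tibble(
        intensity = k, trial = tr,
        peak_soma = pa_s$peak, area_soma = pa_s$area,
        peak_dend = pa_d$peak, area_dend = pa_d$area)
    }
  }
  trials_tbl <- bind_rows(rows)
  summ <- trials_tbl |>
    group_by(.data$intensity) |>
    summarise(across(all_of(c("peak_soma", "area_soma", "peak_dend", "area_dend")),
                     list(mean = mean, sd = sd)), .groups = "drop")
  structure(list(summary = summ, trials = trials_tbl, site = site,
                 onset = onset, response_ms = response_ms, dt = dt, seed = seed),
            class = "pir_io_curve")
}

#' Detect the local-spike threshold of an input-output curve
#'
#' Fits a four-parameter logistic to mean peak versus intensity and compares
#' it with a straight line by AIC. If the sigmoid wins, the threshold
#' intensity is the fitted inflection point and the threshold voltage the
#' mean peak at the largest intensity below it; otherwise no spike is
#' detected.
#'
#' @param curve a `pir_io_curve`.
#' @param measure `"soma"` (default) or `"dend"`: which recorded peak to fit.
#' @return list with `detected`, `threshold_intensity`, `threshold_voltage`,
#'   and the fitted model.
#' @export
detect_threshold <- function(curve, measure = c("soma", "dend")) {
  measure <- match.arg(measure)
  col <- paste0("peak_", measure, "_mean")
  x <- curve$summary$intensity
  y <- curve$summary[[col]]
  no_spike <- list(detected = FALSE, threshold_intensity = NA_real_,
                   threshold_voltage = NA_real_, fit = NULL)
  if (max(y) - min(y) < 1e-9) return(no_spike)
  lin <- lm(y ~ x)
  fit <- tryCatch(nls(y ~ SSfpl(x, lo, hi, xmid, scal)),
                  error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to an explicitly parameterised fit with bounded steepness
    fit <- tryCatch(
      nls(y ~ lo + (hi - lo) / (1 + exp(-(x - xmid) / scal)),
          start = list(lo = min(y), hi = max(y), scal = diff(range(x)) / 10,
                       xmid = x[which.min(abs(y - (min(y) + max(y)) / 2))]),
          algorithm = "port",
          lower = c(lo = -Inf, hi = -Inf, scal = 1e-3, xmid = min(x)),
          upper = c(lo = Inf, hi = Inf, scal = diff(range(x)), xmid = max(x)),
          control = list(warnOnly = TRUE)),
      error = function(e) NULL)
  }
  if (is.null(fit) || AIC(fit) >= AIC(lin)) return(no_spike)
  cf <- coef(fit)
  # require an increasing sigmoid with a positive amplitude
  if (cf[["scal"]] <= 0 || cf[["hi"]] <= cf[["lo"]]) return(no_spike)
  th <- unname(cf[["xmid"]])
  if (th < min(x) || th > max(x)) return(no_spike)
  below <- x[x < th]
  thv <- if (length(below) > 0) y[x == max(below)] else NA_real_
  list(detected = TRUE, threshold_intensity = th,
       threshold_voltage = unname(thv), fit = fit)
}

#' Bias-input pairing experiment
#'
#' Measures how a constant subthreshold "bias" input shifts the
#' input-output curve of a "driver" input: the driver's curve is generated
#' alone and in the presence of the bias burst (optionally time-shifted),
#' thresholds are extracted with [detect_threshold()], and the percent
#' threshold reduction is returned. The branch relation between the two
#' sites (same / sister / different) is reported from the morphology.
#'
#' @param system a `pir_system`.
#' @param driver,bias [stimulus_site()]s; `bias$n_synapses` sets the bias
#'   intensity unless `bias_intensity` is given.
#' @param bias_intensity number of bias synapses.
#' @param time_shift shift of the bias burst relative to the driver, ms.
#' @param intensities driver intensities (synapse counts).
#' @param trials trials per intensity.
#' @param seed,dt,onset,response_ms see [io_curve()].
#' @param max_bias_local_mv guard: the bias alone must stay below this local
#'   depolarization (i.e. subthreshold), else a protocol error is raised.
#' @param deterministic_release replace release sampling by its expectation
#'   in both curves (mean-field threshold mapping).
#' @return a `pir_pairing`: unpaired and paired curves, thresholds, percent
#'   threshold reduction, bias somatic EPSP, and the branch relation.
#' @export
pairing_experiment <- function(system, driver, bias, bias_intensity = NULL,
                               time_shift = 0, intensities = 0:12, trials = 2,
                               seed = 1, dt = 0.025, onset = 50,
                               response_ms = 300, max_bias_local_mv = 40,
                               deterministic_release = FALSE) {
  nb <- bias_intensity %||% bias$n_synapses
  duration <- onset + response_ms
  bias_syn <- NULL
  bias_trains <- NULL
  bias_epsp <- 0
  if (nb > 0) {
    bias_syn <- site_synapses(bias, nb, bias$scale, "bias", system$grid)
    bt <- burst_times(onset + time_shift, bias$pulses, bias$pulse_hz)
    bias_trains <- setNames(rep(list(bt), nb), paste0("bias_", seq_len(nb)))
    # the bias alone must be subthreshold
    sysb <- set_synapses(system, bias_syn, bias_trains)
    bcomp <- resolve_comp(system$grid, bias$location)
    simb <- run_simulation(sysb, duration, dt = dt, seed = seed,
                           record = list("soma", bcomp),
                           deterministic_release = TRUE)
    pa_local <- peak_and_area(get_trace(simb, 2), c(0, onset - 2), c(onset, duration))
    if (pa_local$peak > max_bias_local_mv) {
      abort("bias input is suprathreshold on its own", class = "pir_protocol_error")
    }
    bias_epsp <- peak_and_area(get_trace(simb, 1), c(0, onset - 2),
                               c(onset, duration))$peak
  }

  unpaired <- io_curve(system, driver, intensities, trials = trials, seed = seed,
                       dt = dt, onset = onset, response_ms = response_ms,
                       deterministic_release = deterministic_release)
  paired <- io_curve(system, driver, intensities, trials = trials, seed = seed,
                     dt = dt, onset = onset, response_ms = response_ms,
                     extra_synapses = bias_syn, extra_trains = bias_trains,
                     deterministic_release = deterministic_release)
  th_u <- detect_threshold(unpaired)
  th_p <- detect_threshold(paired)
  red <- if (th_u$detected && th_p$detected) {
    threshold_reduction(th_u$threshold_intensity, th_p$threshold_intensity)
  } else NA_real_
  structure(list(
    unpaired = unpaired, paired = paired,
    threshold_unpaired = th_u, threshold_paired = th_p,
    reduction_pct = red, bias_epsp = bias_epsp, time_shift = time_shift,
    relation = branch_relation(system$grid$morph, driver$location, bias$location)
  ), class = "pir_pairing")
}

#' Clustered versus dispersed synaptic drive
#'
#' Distributes `n_signal_exc` stimulus-encoding excitatory inputs over the
#' LOT-recipient zone, a fraction `clustering_fraction` of them concentrated
#' on a single terminal LOT branch and the rest dispersed over all LOT
#' branches, plus `n_signal_inh` inhibitory inputs split between the distal
#' LOT band (feedforward) and the perisomatic region (feedback). Each trial
#' also carries the 120-input background population; the presynaptic trains
#' are driven by the trial seed only, so matched trials at different
#' clustering fractions see identical spike trains. The somatic response is
#' measured as peak (and area) above the background-only trace of the same
#' trial.
#'
#' @param system a `pir_system`.
#' @param n_signal_exc,n_signal_inh signal population sizes.
#' @param clustering_fraction fraction of excitatory inputs in the clustered
#'   pool, in `[0, 1]`.
#' @param ohmic freeze the NMDA voltage dependence (control condition).
#' @param trials number of trials.
#' @param seed integer seed; the clustered target branch is drawn from it.
#' @param scale conductance scale of signal synapses.
#' @param n_bg_exc,n_bg_inh,bg_rate background population.
#' @param dt,duration integration parameters, ms.
#' @param inh_ff_fraction fraction of signal inhibition placed distally
#'   (feedforward) rather than perisomatically.
#' @param cluster_section optional section id for the clustered pool.
#' @return a `pir_cvd`: per-trial tibble of background-subtracted somatic
#'   peak and area, plus metadata.
#' @export
clustered_vs_dispersed <- function(system, n_signal_exc = 20, n_signal_inh = 40,
                                   clustering_fraction = 1, ohmic = FALSE,
                                   trials = 100, seed = 1, scale = 1,
                                   n_bg_exc = 100, n_bg_inh = 20, bg_rate = 10,
                                   dt = 0.025, duration = 500,
                                   inh_ff_fraction = 0.5,
                                   cluster_section = NULL) {
  stopifnot(clustering_fraction >= 0, clustering_fraction <= 1)
  grid <- system$grid
  morph <- grid$morph
  if (ohmic) system <- set_ohmic_nmda(system, TRUE)

  # choose the clustered target branch: a terminal section reaching the LOT
  # zone
  term <- terminal_sections(morph)
  tipd <- section_tip_distances(morph)
  lot_term <- term[tipd$tip_dist[match(term, tipd$section)] >= 250]
  if (length(lot_term) == 0) abort("no terminal LOT branch available",
                                   class = "pir_placement_error")
  old <- .Random.seed_save()
  set.seed(seed)
  target_sec <- cluster_section %||% sample(lot_term, 1)
  .Random.seed_restore(old)

  n_clust <- round(clustering_fraction * n_signal_exc)
  sec_len <- morph$sections$length[match(target_sec, morph$sections$section)]
  # capacity: ~2 synaptic contacts per um of branch
  if (n_clust > floor(2 * sec_len)) {
    abort("clustered pool exceeds target-branch capacity",
          class = "pir_placement_error")
  }

  trial_seeds <- derive_seeds(seed, trials)
  rows <- vector("list", trials)
  onset <- 100
  for (tr in seq_len(trials)) {
    ts <- trial_seeds[tr]
    old <- .Random.seed_save()
    set.seed(ts)
    # placements
    loc_clust <- if (n_clust > 0) sample_locations(grid, n_clust,
                                                   section = target_sec) else list()
    loc_disp <- if (n_signal_exc - n_clust > 0) {
      sample_locations(grid, n_signal_exc - n_clust, zone = "LOT")
    } else list()
    n_ff <- round(inh_ff_fraction * n_signal_inh)
    loc_inh <- c(
      if (n_ff > 0) sample_locations(grid, n_ff, zone = "LOT") else list(),
      if (n_signal_inh - n_ff > 0)
        sample_locations(grid, n_signal_inh - n_ff, zone = "perisomatic") else list())
    # trains (drawn before any placement-dependent randomness would differ)
    exc_trains <- lapply(seq_len(n_signal_exc), function(i)
      generate_train(100, 6, 8, 5, 5, 3))
    inh_trains <- lapply(seq_len(length(loc_inh)), function(i)
      generate_train(110, 6, 8, 5, 10, 3))
    .Random.seed_restore(old)

    syn_sig <- bind_rows(
      if (n_signal_exc > 0)
        synapse_population(c(loc_clust, loc_disp), type = "exc", scale = scale,
                           input_prefix = "sig_exc"),
      if (length(loc_inh) > 0)
        synapse_population(loc_inh, type = "inh", input_prefix = "sig_inh"))
    trains_sig <- c(setNames(exc_trains, paste0("sig_exc_", seq_len(n_signal_exc))),
                    setNames(inh_trains, paste0("sig_inh_", seq_along(loc_inh))))

    bg <- generate_background(grid, n_bg_exc, n_bg_inh, bg_rate, duration,
                              seed = ts + 7L)

    sys_sig <- set_synapses(system, bind_rows(syn_sig, bg$synapses),
                            c(trains_sig, bg$trains))
    sys_bg <- set_synapses(system, bg$synapses, bg$trains)
    sim_sig <- run_simulation(sys_sig, duration, dt = dt, seed = ts)
    sim_bg <- run_simulation(sys_bg, duration, dt = dt, seed = ts)
    diffd <- background_subtract(get_trace(sim_sig, 1), get_trace(sim_bg, 1))
    sel <- diffd$time >= onset
    rows[[tr]] <- tibble(trial = tr,
                         peak = max(diffd$v[sel]),
                         area = trapz_int(diffd$time[sel], diffd$v[sel]))
  }
  structure(list(trials = bind_rows(rows),
                 clustering_fraction = clustering_fraction, ohmic = ohmic,
                 n_signal_exc = n_signal_exc, n_signal_inh = n_signal_inh,
                 target_section = target_sec, seed = seed),
            class = "pir_cvd")
}

#' Glomerulus specification for combination-selectivity runs
#'
#' @param label glomerulus label ("A", "B", ...).
#' @param n_inputs presynaptic cells contributed by the glomerulus.
#' @param section target section id (assigned by
#'   [glomerular_combination()] when `NULL`).
#' @export
glomerulus_spec <- function(label, n_inputs = 6, section = NULL) {
  stopifnot(n_inputs > 0)
  list(label = label, n_inputs = n_inputs, section = section)
}

#' Glomerular combination selectivity
#'
#' Three glomeruli (six inputs each by default): A and B target the same
#' terminal apical dendrite, C a terminal branch of a different primary
#' dendrite. Per trial, the somatic response is simulated for background
#' only, each single glomerulus, and the AB and AC pairs, with background
#' and glomerular trains matched across conditions; the pairing nonlinearity
#' ratio (AUC of the background-subtracted pair over AUC of the expected
#' linear sum) and the background-subtracted peak/area are computed for both
#' pairs. 24 odor-unselective inhibitory synapses are active in every
#' odor-carrying condition.
#'
#' @param system a `pir_system`.
#' @param gloms list of [glomerulus_spec()]s (default A, B, C as above).
#' @param pairs list of label pairs to test.
#' @param trials number of trials.
#' @param seed integer seed.
#' @param scale conductance scale of glomerular synapses.
#' @param n_inh unselective inhibitory synapses.
#' @param dt,duration integration parameters, ms.
#' @param min_expected_auc exclusion floor for near-zero expected-linear
#'   areas (mV ms), see [pairing_nonlinearity()].
#' @param keep_traces return the somatic traces of the first trial.
#' @return a `pir_glom`: per-trial tibble with ratios and peaks per pair,
#'   plus metadata (and optionally example traces).
#' @export
glomerular_combination <- function(system, gloms = NULL,
                                   pairs = list(c("A", "B"), c("A", "C")),
                                   trials = 20, seed = 1, scale = 1,
                                   n_inh = 24, dt = 0.025, duration = 500,
                                   min_expected_auc = 50,
                                   keep_traces = FALSE) {
  grid <- system$grid
  morph <- grid$morph
  if (is.null(gloms)) {
    gloms <- list(glomerulus_spec("A"), glomerulus_spec("B"), glomerulus_spec("C"))
  }
  labels <- vapply(gloms, `[[`, character(1), "label")
  for (p in pairs) {
    if (!all(p %in% labels)) abort("unknown glomerulus label in pairs",
                                   class = "pir_lookup_error")
  }

  # default placement: A and B share one terminal LOT section, C sits on a
  # terminal section of a different primary dendrite
  term <- terminal_sections(morph)
  tipd <- section_tip_distances(morph)
  lot_term <- term[tipd$tip_dist[match(term, tipd$section)] >= 250]
  roots <- morph$sections$root_id[match(lot_term, morph$sections$section)]
  tips <- tipd$tip_dist[match(lot_term, tipd$section)]
  # glomerular targets: the most distal terminal of two distinct primary
  # dendrites (distal LOT innervation, maximal electrotonic separation)
  sec_ab <- lot_term[which.max(tips)]
  other <- roots != roots[match(sec_ab, lot_term)]
  sec_c <- lot_term[other][which.max(tips[other])]
  defaults <- c(A = sec_ab, B = sec_ab, C = sec_c)
  for (i in seq_along(gloms)) {
    if (is.null(gloms[[i]]$section)) gloms[[i]]$section <-
        unname(defaults[gloms[[i]]$label])
  }

  onset <- 100
  trial_seeds <- derive_seeds(seed, trials)
  rows <- vector("list", trials)
  traces <- NULL
  singles <- as.list(labels)
  conds <- c(list(character(0)), singles, pairs)
  cond_names <- vapply(conds, function(s) if (length(s) == 0) "bg" else
    paste(s, collapse = ""), character(1))

  for (tr in seq_len(trials)) {
    ts <- trial_seeds[tr]
    old <- .Random.seed_save()
    set.seed(ts)
    glom_syn <- list(); glom_trains <- list()
    for (g in gloms) {
      locs <- sample_locations(grid, g$n_inputs, section = g$section)
      pref <- paste0("glom", g$label)
      glom_syn[[g$label]] <- synapse_population(locs, type = "exc",
                                                scale = scale,
                                                input_prefix = pref)
      glom_trains[[g$label]] <- setNames(
        lapply(seq_len(g$n_inputs), function(i) generate_train(100, 6, 8, 5, 5, 3)),
        paste0(pref, "_", seq_len(g$n_inputs)))
    }
    loc_inh <- c(sample_locations(grid, ceiling(n_inh / 2), zone = "LOT"),
                 sample_locations(grid, floor(n_inh / 2), zone = "perisomatic"))
    inh_syn <- synapse_population(loc_inh, type = "inh", input_prefix = "uinh")
    inh_trains <- setNames(lapply(seq_len(n_inh), function(i)
      generate_train(110, 6, 8, 5, 10, 3)), paste0("uinh_", seq_len(n_inh)))
    .Random.seed_restore(old)

    bg <- generate_background(grid, duration = duration, seed = ts + 13L)

    run_cond <- function(active) {
      syn <- bg$synapses
      trains <- bg$trains
      if (length(active) > 0) {
        syn <- bind_rows(syn, inh_syn, bind_rows(glom_syn[active]))
        trains <- c(trains, inh_trains, unlist(glom_trains[active],
                                               recursive = FALSE,
                                               use.names = FALSE))
        names(trains) <- c(names(bg$trains), names(inh_trains),
                           unlist(lapply(glom_trains[active], names)))
      }
      sim <- run_simulation(set_synapses(system, syn, trains), duration,
                            dt = dt, seed = ts)
      get_trace(sim, 1)
    }
    tr_cond <- lapply(conds, run_cond)
    names(tr_cond) <- cond_names

    out <- tibble(trial = tr)
    win <- c(onset - 10, duration)
    for (p in pairs) {
      pname <- paste(p, collapse = "")
      ratio <- pairing_nonlinearity(tr_cond[[pname]], tr_cond[[p[1]]],
                                    tr_cond[[p[2]]], tr_cond$bg, win,
                                    min_expected_auc = min_expected_auc)
      diffp <- background_subtract(tr_cond[[pname]], tr_cond$bg)
      sel <- diffp$time >= win[1]
      out[[paste0("ratio_", pname)]] <- ratio
      out[[paste0("peak_", pname)]] <- max(diffp$v[sel])
      out[[paste0("area_", pname)]] <- trapz_int(diffp$time[sel], diffp$v[sel])
    }
    rows[[tr]] <- out
    if (keep_traces && tr == 1) traces <- tr_cond
  }
  structure(list(trials = bind_rows(rows), gloms = gloms, pairs = pairs,
                 traces = traces, seed = seed),
            class = "pir_glom")
}
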