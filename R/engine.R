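#' Assemble a compartmental electrical system
#'
#' Combines a discretized morphology with passive membrane properties,
#' optional voltage-gated channels, and a synapse population with its
#' presynaptic trains into the state needed by the integrator.
#'
#' `unitary_meaning` fixes how the published unitary conductances map onto
#' the five-vesicle stochastic pool: `"event_mean"` (default) reads them as
#' the conductance of the *average* release event (`n_slots * Pr` = 0.5
#' vesicles), so per-vesicle conductance is `g_unit / (n_slots * Pr)`;
#' `"full_pool"` reads them as a full five-vesicle release
#' (`g_unit / n_slots` per vesicle); `"per_vesicle"` applies `g_unit` to
#' each vesicle. The `event_mean` reading is the one consistent with the
#' reported background depolarization and is applied uniformly; the GABA-A
#' reading can be switched independently via `gaba_meaning` (see the
#' package vignette for the reasoning).
#'
#' @param grid a `pir_grid` from [discretize()].
#' @param passive a [passive_params()].
#' @param channels a [channel_set()], or `NULL` for a passive membrane
#'   (protocol measurements are subthreshold EPSPs; see the vignette).
#' @param synapses synapse component tibble ([synapse_population()]).
#' @param trains named list of presynaptic spike-time vectors (ms), one per
#'   `input_id`.
#' @param unitary_meaning see above.
#' @param gaba_meaning reading of the GABA-A unitary conductance (see above).
#' @param ohmic_nmda if `TRUE`, the NMDA gating factor is frozen at
#'   `ohmic_vm` (voltage independence; the "Ohmic NMDA" control).
#' @param ohmic_vm voltage at which the frozen gating factor is evaluated.
#' @param balance_rest inject a constant per-compartment bias current that
#'   cancels the resting-state channel current, so `E_rest` remains the
#'   resting potential with channels inserted.
#' @return a `pir_system`.
#' @export
compartmental_system <- function(grid, passive = passive_params(),
                                 channels = NULL, synapses = NULL,
                                 trains = NULL,
                                 unitary_meaning = c("event_mean", "full_pool",
                                                     "per_vesicle"),
                                 gaba_meaning = "event_mean",
                                 ohmic_nmda = FALSE, ohmic_vm = -70,
                                 balance_rest = TRUE) {
  unitary_meaning <- match.arg(unitary_meaning)
  gaba_meaning <- match.arg(gaba_meaning,
                            c("event_mean", "full_pool", "per_vesicle"))
  cc <- grid$comps
  n <- nrow(cc)
  cap <- passive$Cm * cc$area * 1e-5            # nF
  g_leak <- cc$area * 1e-2 / passive$Rm         # uS
  e_leak <- rep(passive$E_rest, n)
  parent <- ifelse(is.na(cc$parent_comp), -1L, cc$parent_comp - 1L)
  g_ax <- ifelse(is.na(cc$g_axial), 0, cc$g_axial)

  gna <- gkdr <- gks <- numeric(n)
  chan_meta <- list(ena = 50, ek = -87, vt = -55, ks_vhalf = -10,
                    ks_slope = 10, ks_taumax = 2025)
  if (!is.null(channels)) {
    mask <- channel_mask(channels$placement, n)
    dens_to_us <- cc$area * 1e-5  # mS/cm^2 -> uS
    gna[mask] <- channels$gNa * dens_to_us[mask]
    gkdr[mask] <- channels$gKdr * dens_to_us[mask]
    gks[mask] <- channels$gKs * dens_to_us[mask]
    chan_meta <- list(ena = channels$ENa, ek = channels$EK, vt = channels$VT,
                      ks_vhalf = channels$ks_vhalf, ks_slope = channels$ks_slope,
                      ks_taumax = channels$ks_taumax)
  }
  i_bias <- numeric(n)
  if (!is.null(channels) && balance_rest) {
    g0 <- steady_gating(passive$E_rest, channels)
    i_bias <- gna * g0$m^3 * g0$h * (passive$E_rest - channels$ENa) +
      (gkdr * g0$n^4 + gks * g0$p) * (passive$E_rest - channels$EK)
    # uS * mV = nA; injected with opposite sign convention folded in below
  }

  if (!is.null(synapses)) synapses <- check_synapses(grid, synapses)

  structure(list(
    grid = grid, passive = passive, channels = channels,
    synapses = synapses, trains = trains,
    unitary_meaning = unitary_meaning, gaba_meaning = gaba_meaning,
    ohmic_nmda = ohmic_nmda, ohmic_vm = ohmic_vm,
    n = n, parent = parent, g_ax = g_ax, cap = cap, g_leak = g_leak,
    e_leak = e_leak, i_bias = i_bias,
    gna = gna, gkdr = gkdr, gks = gks, chan_meta = chan_meta
  ), class = "pir_system")
}

channel_mask <- function(placement, n) {
  if (is.character(placement)) {
    switch(placement,
           soma = 1L,
           all = seq_len(n),
           abort("unknown channel placement", class = "pir_lookup_error"))
  } else as.integer(placement)
}

check_synapses <- function(grid, synapses) {
  ok <- synapses$section %in% grid$comps$section
  if (!all(ok)) abort("synapse location refers to a section absent from the grid",
                      class = "pir_lookup_error")
  synapses
}

#' Replace the synapse population of a system
#'
#' @param system a `pir_system`.
#' @param synapses synapse component tibble.
#' @param trains named list of spike-time vectors.
#' @export
set_synapses <- function(system, synapses, trains) {
  system$synapses <- if (is.null(synapses)) NULL else
    check_synapses(system$grid, synapses)
  system$trains <- trains
  system
}

#' Freeze (or unfreeze) the NMDA voltage dependence
#'
#' With the flag on, the NMDA gating factor is evaluated at a fixed
#' `ohmic_vm` (default -70 mV) for the whole simulation, removing the
#' regenerative nonlinearity while preserving the kinetic waveform.
#'
#' @param system a `pir_system`.
#' @param flag logical.
#' @param ohmic_vm frozen evaluation voltage, mV.
#' @export
set_ohmic_nmda <- function(system, flag = TRUE, ohmic_vm = -70) {
  system$ohmic_nmda <- flag
  system$ohmic_vm <- ohmic_vm
  system
}

#' Resolve a recording/stimulation site to a compartment index
#'
#' @param grid a `pir_grid`.
#' @param site `"soma"`, a [dendritic_location()], or a compartment index.
#' @export
resolve_comp <- function(grid, site) {
  if (is.numeric(site)) return(as.integer(site))
  if (identical(site, "soma")) return(1L)
  if (inherits(site, "pir_location")) {
    cc <- grid$comps
    cand <- which(cc$section == site$section)
    if (length(cand) == 0) abort("unknown section id", class = "pir_lookup_error")
    hit <- cand[site$arc >= cc$arc0[cand] & site$arc <= cc$arc1[cand]]
    return(if (length(hit) > 0) hit[1] else cand[length(cand)])
  }
  abort("cannot resolve site", class = "pir_lookup_error")
}

per_vesicle_divisor <- function(meaning, n_slots, pr) {
  switch(meaning,
         event_mean = n_slots * pr,
         full_pool = n_slots,
         per_vesicle = 1)
}

unitary_meaning_for <- function(system, kind) {
  if (kind == "gabaa") system$gaba_meaning else system$unitary_meaning
}

#' Integrate the compartmental system
#'
#' Solves the branched cable equation with an implicit theta-rule step
#' (Crank-Nicolson by default) and a Hines-ordered direct tree solve.
#' Vesicular release is simulated per synapse from its presynaptic train
#' before integration (release does not depend on voltage), with one
#' independent RNG substream per presynaptic input derived from `seed`, so
#' release sequences are reproducible regardless of synapse order.
#'
#' @param system a `pir_system`.
#' @param duration simulated time, ms.
#' @param dt time step, ms; must be in (0, 0.1].
#' @param seed integer seed for release sampling.
#' @param record sites to record: a list of `"soma"` /
#'   [dendritic_location()] / compartment indices (`"all"` records every
#'   compartment).
#' @param clamp optional voltage clamp: `list(site =, hold =)` (mV). The
#'   clamp current trace is returned in nA; inward synaptic current appears
#'   as negative electrode current.
#' @param inject optional current injections: tibble/data.frame with
#'   `site` (list-column or comp index), `start`, `stop` (ms), `amp` (nA).
#' @param deterministic_release replace release sampling by its expectation.
#' @param theta implicitness parameter (0.5 = Crank-Nicolson, 1 = backward
#'   Euler).
#' @return a `pir_sim`: list with `time` (ms), `v` (matrix, one column per
#'   recorded site), `i_clamp` (nA, if clamped), `releases` (per-input
#'   vesicle counts), `seed`, `dt`, and a config hash.
#' @export
run_simulation <- function(system, duration, dt = 0.025, seed = NULL,
                           record = list("soma"), clamp = NULL, inject = NULL,
                           deterministic_release = FALSE, theta = 0.5) {
  stopifnot(dt > 0, dt <= 0.1, duration > 0)
  grid <- system$grid
  n_steps <- as.integer(ceiling(duration / dt))

  if (identical(record, "all") || identical(record, list("all"))) {
    rec_idx <- seq_len(system$n)
  } else {
    if (!is.list(record)) record <- list(record)
    rec_idx <- vapply(record, function(s) resolve_comp(grid, s), integer(1))
  }

  # --- presynaptic release, one substream per input
  syn <- system$synapses
  ev_syn <- integer(0); ev_step <- integer(0); ev_g <- numeric(0)
  syn_comp <- integer(0); syn_taur <- syn_taud <- syn_erev <- numeric(0)
  syn_nmda <- logical(0)
  releases <- NULL
  if (!is.null(syn) && nrow(syn) > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    if (!is.null(seed)) set.seed(seed)
    inputs <- unique(syn$input_id)
    sub_seeds <- sample.int(2147483646L, length(inputs))
    syn_comp <- vapply(seq_len(nrow(syn)), function(i) {
      resolve_comp(grid, dendritic_location(syn$section[i], syn$arc[i]))
    }, integer(1)) - 1L
    syn_taur <- syn$tau_rise
    syn_taud <- syn$tau_decay
    syn_erev <- syn$e_rev
    syn_nmda <- syn$kind == "nmda"

    evs <- vector("list", length(inputs))
    rel_counts <- numeric(length(inputs))
    for (k in seq_along(inputs)) {
      id <- inputs[k]
      tt <- system$trains[[id]]
      if (is.null(tt) || length(tt) == 0) next
      rows <- which(syn$input_id == id)
      r1 <- rows[1]
      set.seed(sub_seeds[k])
      rel <- simulate_release_train(
        tt, release_state(n_slots = syn$n_slots[r1], Pr = syn$pr[r1],
                          replenish_rate = syn$replenish_rate[r1]),
        deterministic = deterministic_release)
      rel <- rel[rel$released > 0 & rel$time <= duration, , drop = FALSE]
      rel_counts[k] <- sum(rel$released)
      if (nrow(rel) == 0) next
      steps <- pmax(1L, pmin(n_steps, as.integer(round(rel$time / dt))))
      per_row <- lapply(rows, function(r) {
        gpv <- syn$scale[r] * syn$g_unit[r] /
          per_vesicle_divisor(unitary_meaning_for(system, syn$kind[r]),
                              syn$n_slots[r], syn$pr[r])
        tibble(syn = r - 1L, step = steps, g = rel$released * gpv * 1e-3) # uS
      })
      evs[[k]] <- bind_rows(per_row)
    }
    ev <- bind_rows(evs)
    if (!is.null(ev) && nrow(ev) > 0) {
      ev <- ev[order(ev$step), , drop = FALSE]
      ev_syn <- ev$syn; ev_step <- ev$step; ev_g <- ev$g
    }
    releases <- tibble(input_id = inputs, vesicles = rel_counts)
  }

  # --- clamp / injections
  clamp_comp <- -1L; clamp_v <- 0
  if (!is.null(clamp)) {
    clamp_comp <- resolve_comp(grid, clamp$site) - 1L
    clamp_v <- clamp$hold
  }
  inj_comp <- integer(0); inj_from <- integer(0); inj_to <- integer(0)
  inj_amp <- numeric(0)
  if (!is.null(inject) && nrow(inject) > 0) {
    inj_comp <- vapply(seq_len(nrow(inject)), function(i) {
      s <- if (is.list(inject$site)) inject$site[[i]] else inject$site[i]
      resolve_comp(grid, s)
    }, integer(1)) - 1L
    inj_from <- pmax(1L, as.integer(ceiling(inject$start / dt)))
    inj_to <- pmin(n_steps, as.integer(floor(inject$stop / dt)))
    inj_amp <- inject$amp
  }

  cm <- system$chan_meta
  res <- cpp_integrate(
    system$n, system$parent, system$g_ax, system$cap, system$g_leak,
    system$e_leak, system$i_bias,
    system$gna, system$gkdr, system$gks,
    cm$ena, cm$ek, cm$vt, cm$ks_vhalf, cm$ks_slope, cm$ks_taumax,
    syn_comp, syn_taur, syn_taud, syn_erev, syn_nmda,
    ev_syn, ev_step, ev_g,
    system$ohmic_nmda, system$ohmic_vm,
    inj_comp, inj_from, inj_to, inj_amp,
    clamp_comp, clamp_v,
    system$passive$E_rest, dt, n_steps,
    rec_idx - 1L, theta)

  time <- seq(0, by = dt, length.out = n_steps + 1)
  v <- res$v
  colnames(v) <- paste0("comp", rec_idx)
  i_clamp <- NULL
  if (clamp_comp >= 0) {
    i_clamp <- res$i_clamp
    i_clamp[1] <- i_clamp[2]
  }
  structure(list(
    time = time, v = v, sites = rec_idx, i_clamp = i_clamp,
    releases = releases, seed = seed, dt = dt, duration = duration,
    config_hash = rlang::hash(list(system$unitary_meaning, system$ohmic_nmda,
                                   system$n, seed, dt, duration))
  ), class = "pir_sim")
}

#' Extract a recorded voltage trace as a tibble
#'
#' @param sim a `pir_sim`.
#' @param site recorded site (as passed to [run_simulation()]), or a column
#'   index into the recording matrix.
#' @param grid grid used to resolve non-integer sites (defaults to column 1).
#' @return tibble with `time` (ms) and `v` (mV).
#' @export
get_trace <- function(sim, site = 1, grid = NULL) {
  col <- if (is.numeric(site) && length(site) == 1 && site <= ncol(sim$v) &&
             is.null(grid)) {
    as.integer(site)
  } else {
    idx <- resolve_comp(grid, site)
    match(idx, sim$sites)
  }
  if (is.na(col)) abort("site was not recorded", class = "pir_lookup_error")
  tibble(time = sim$time, v = sim$v[, col])
}

#' Voltage-clamp a site and return the clamp current trace
#'
#' Convenience wrapper over [run_simulation()] with a somatic (or arbitrary)
#' voltage clamp. The returned `i_clamp` is the electrode current (nA)
#' required to hold the command potential; inward synaptic current is
#' negative.
#'
#' @param system a `pir_system`.
#' @param site clamp site.
#' @param hold command potential, mV.
#' @param ... passed to [run_simulation()].
#' @export
voltage_clamp <- function(system, site = "soma", hold = -70, ...) {
  run_simulation(system, clamp = list(site = site, hold = hold), ...)
}

#' @export
print.pir_sim <- function(x, ...) {
  cat("<pir_sim> ", sprintf("%.0f", x$duration), " ms at dt ", x$dt,
      " ms, ", ncol(x$v), " recorded site(s)",
      if (!is.null(x$i_clamp)) ", voltage-clamped" else "", "\n", sep = "")
  invisible(x)
}
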