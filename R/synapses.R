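#' Synaptic kinetic defaults
#'
#' Receptor kinetics and printed unitary conductances: AMPA instantaneous
#' rise / 1.5 ms decay / 1 nS / 0 mV reversal; NMDA 2 ms rise / 80 ms decay
#' / 2 nS / 0 mV (times the voltage-dependent gating factor,
#' [nmda_gating()]); GABA-A instantaneous rise / 7 ms decay / 2 nS / -70 mV.
#'
#' @return tibble with one row per receptor kind.
#' @export
synapse_kinetics <- function() {
  tibble(
    kind = c("ampa", "nmda", "gabaa"),
    tau_rise = c(0, 2, 0),
    tau_decay = c(1.5, 80, 7),
    e_rev = c(0, 0, -70),
    g_unit = c(1, 2, 2)
  )
}

#' Construct a synapse specification
#'
#' One receptor component at one dendritic location. Excitatory inputs are
#' usually built with [synapse_population()], which colocalises an AMPA and
#' an NMDA component sharing one presynaptic cell and release sequence.
#'
#' @param kind `"ampa"`, `"nmda"`, or `"gabaa"`.
#' @param location a [dendritic_location()].
#' @param g_unit unitary conductance (nS); defaults to the printed value for
#'   `kind`.
#' @param tau_rise,tau_decay rise/decay time constants (ms); 0 rise means an
#'   instantaneous-rise single exponential.
#' @param e_rev reversal potential (mV).
#' @export
synapse_spec <- function(kind, location, g_unit = NULL, tau_rise = NULL,
                         tau_decay = NULL, e_rev = NULL) {
  k <- synapse_kinetics()
  i <- match(kind, k$kind)
  if (is.na(i)) abort("unknown synapse kind", class = "pir_lookup_error")
  spec <- list(kind = kind, location = location,
               g_unit = g_unit %||% k$g_unit[i],
               tau_rise = tau_rise %||% k$tau_rise[i],
               tau_decay = tau_decay %||% k$tau_decay[i],
               e_rev = e_rev %||% k$e_rev[i])
  if (!(spec$tau_decay > spec$tau_rise) || spec$tau_rise < 0 || spec$g_unit < 0) {
    abort("need tau_decay > tau_rise >= 0 and g_unit >= 0",
          class = "pir_constraint_error")
  }
  structure(spec, class = "pir_synapse_spec")
}

#' Synaptic conductance at given elapsed times since release events
#'
#' Reference kinetic waveform: single-exponential decay when `tau_rise` is
#' 0, otherwise a dual exponential normalised so its peak equals
#' `g_unit * released_fraction`. Responses to multiple release events add
#' linearly; the NMDA voltage-dependence factor is applied to the summed
#' conductance at the compartment's membrane potential.
#'
#' @param spec a [synapse_spec()].
#' @param released_fraction fraction of the vesicle pool released per event
#'   (scalar or one per event), in `[0, 1]`.
#' @param elapsed vector of elapsed times since each release event (ms);
#'   negative values (event not yet occurred) contribute nothing.
#' @param Vm local membrane potential (mV), used for NMDA gating.
#' @return conductance in nS.
#' @export
conductance_step <- function(spec, released_fraction, elapsed, Vm = -70) {
  if (length(elapsed) == 0) return(0)
  frac <- rep_len(released_fraction, length(elapsed))
  g <- 0
  for (i in seq_along(elapsed)) {
    t <- elapsed[i]
    if (t < 0) next
    if (spec$tau_rise == 0) {
      w <- exp(-t / spec$tau_decay)
    } else {
      tp <- log(spec$tau_decay / spec$tau_rise) * spec$tau_decay *
        spec$tau_rise / (spec$tau_decay - spec$tau_rise)
      norm <- 1 / (exp(-tp / spec$tau_decay) - exp(-tp / spec$tau_rise))
      w <- norm * (exp(-t / spec$tau_decay) - exp(-t / spec$tau_rise))
    }
    g <- g + spec$g_unit * frac[i] * w
  }
  if (spec$kind == "nmda") g <- g * nmda_gating(Vm)
  g
}

#' Presynaptic vesicle pool state
#'
#' Each synapse holds `n_slots` vesicles (default 5), each released
#' independently with probability `Pr` (default 0.1) when the presynaptic
#' cell fires; emptied slots refill stochastically at `replenish_rate`
#' (default 100 per second).
#'
#' @param n_slots vesicle slots per synapse.
#' @param available currently filled slots.
#' @param Pr per-vesicle release probability.
#' @param replenish_rate refill rate per empty slot, s^-1.
#' @export
release_state <- function(n_slots = 5, available = n_slots, Pr = 0.1,
                          replenish_rate = 100) {
  stopifnot(available >= 0, available <= n_slots, Pr >= 0, Pr <= 1,
            replenish_rate >= 0)
  structure(list(n_slots = as.integer(n_slots), available = as.integer(available),
                 Pr = Pr, replenish_rate = replenish_rate),
            class = "pir_release_state")
}

#' Sample vesicular release at a presynaptic spike
#'
#' Released count is Binomial(available, Pr); the pool is decremented.
#'
#' @param state a [release_state()].
#' @return list with `released` (integer) and the updated `state`.
#' @export
sample_release <- function(state) {
  rel <- rbinom(1, state$available, state$Pr)
  state$available <- state$available - rel
  list(released = rel, state = state)
}

#' Replenish the vesicle pool over a time interval
#'
#' Each empty slot refills independently with probability
#' `1 - exp(-rate * dt)` (memoryless per-slot waiting times).
#'
#' @param state a [release_state()].
#' @param dt elapsed time, ms.
#' @return the updated state.
#' @export
replenish <- function(state, dt) {
  stopifnot(dt > 0)
  empty <- state$n_slots - state$available
  if (empty > 0 && state$replenish_rate > 0) {
    p <- 1 - exp(-state$replenish_rate * dt / 1000)
    state$available <- state$available + rbinom(1, empty, p)
  }
  state
}

#' Simulate the release sequence for a whole spike train
#'
#' Runs the vesicle pool across a sorted presynaptic spike train:
#' replenishment over each inter-spike interval, then binomial release.
#'
#' @param times sorted presynaptic spike times, ms.
#' @param state a [release_state()].
#' @param deterministic if `TRUE`, replaces sampling by expectations
#'   (release = available * Pr vesicles, fractional; full replenishment
#'   probability applied as a fraction). Useful for noise-free protocol
#'   checks.
#' @return tibble with `time`, `released` (vesicles), `frac`
#'   (released / n_slots).
#' @export
simulate_release_train <- function(times, state = release_state(),
                                   deterministic = FALSE) {
  n <- length(times)
  released <- numeric(n)
  avail <- as.numeric(state$available)
  prev <- 0
  for (i in seq_len(n)) {
    gap <- times[i] - prev
    prev <- times[i]
    if (gap > 0 && state$replenish_rate > 0) {
      p <- 1 - exp(-state$replenish_rate * gap / 1000)
      empty <- state$n_slots - avail
      avail <- avail + if (deterministic) empty * p else rbinom(1, round(empty), p)
    }
    rel <- if (deterministic) avail * state$Pr else rbinom(1, floor(avail), state$Pr)
    avail <- avail - rel
    released[i] <- rel
  }
  tibble(time = times, released = released, frac = released / state$n_slots)
}

#' Generate a presynaptic spike train
#'
#' Mimics mitral-cell-like burst firing: the spike count is drawn from a
#' normal distribution (rounded, clipped at 0), the burst start from a
#' normal, and inter-spike intervals from a normal truncated below at
#' 0.1 ms. Defaults are the excitatory-train statistics (start 100 +/- 6 ms,
#' ISI 8 +/- 5 ms, count 5 +/- 3); inhibitory trains use start 110 +/- 6 ms
#' and count 10 +/- 3.
#'
#' @param start_mean,start_sd burst start time, ms.
#' @param isi_mean,isi_sd inter-spike interval, ms.
#' @param count_mean,count_sd number of spikes.
#' @param seed optional integer seed (restores the caller's RNG stream).
#' @return sorted numeric vector of spike times (ms).
#' @export
generate_train <- function(start_mean = 100, start_sd = 6,
                           isi_mean = 8, isi_sd = 5,
                           count_mean = 5, count_sd = 3, seed = NULL) {
  stopifnot(start_sd >= 0, isi_sd >= 0, count_sd >= 0)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  count <- max(0L, round(rnorm(1, count_mean, count_sd)))
  if (count == 0L) return(numeric(0))
  start <- max(0, rnorm(1, start_mean, start_sd))
  isis <- pmax(0.1, rnorm(count - 1, isi_mean, isi_sd))
  sort(cumsum(c(start, isis)))
}

#' Generate the in vivo-like background synaptic population
#'
#' 100 excitatory (AMPA-only) and 20 inhibitory (GABA-A) synapses placed
#' uniformly over the apical membrane (probability proportional to membrane
#' area), each driven by an independent homogeneous Poisson train at
#' `rate` Hz. A new seed gives new placements and trains.
#'
#' @param grid a `pir_grid`.
#' @param n_exc,n_inh population sizes.
#' @param rate mean firing rate, Hz.
#' @param duration simulated time covered by the trains, ms.
#' @param seed optional integer seed.
#' @param place_seed optional separate seed for placements, so activation can
#'   be redrawn on a fixed spatial distribution.
#' @return list with `synapses` (component tibble, see
#'   [synapse_population()]) and `trains` (list of spike-time vectors named
#'   by input id).
#' @export
generate_background <- function(grid, n_exc = 100, n_inh = 20, rate = 10,
                                duration = 600, seed = NULL, place_seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  place <- function(n, pseed = NULL) {
    if (!is.null(pseed)) {
      old2 <- .Random.seed_save()
      on.exit(.Random.seed_restore(old2), add = TRUE)
      set.seed(pseed)
    }
    sample_locations(grid, n, zone = "apical")
  }
  loc_exc <- place(n_exc, place_seed)
  loc_inh <- place(n_inh, if (is.null(place_seed)) NULL else place_seed + 1L)
  syn <- bind_rows(
    synapse_population(loc_exc, type = "exc", nmda = FALSE,
                       input_prefix = "bg_exc"),
    synapse_population(loc_inh, type = "inh", input_prefix = "bg_inh")
  )
  trains <- lapply(unique(syn$input_id), function(id) {
    n <- rpois(1, rate * duration / 1000)
    sort(runif(n, 0, duration))
  })
  names(trains) <- unique(syn$input_id)
  list(synapses = syn, trains = trains)
}

#' Sample synapse placements over the dendritic membrane
#'
#' Locations are drawn with probability proportional to compartment membrane
#' area, restricted to a zone: `"apical"` (any dendrite), `"LOT"`, `"IC"`,
#' `"perisomatic"` (dendritic compartments within 100 um), or a specific
#' section id via `section`.
#'
#' @param grid a `pir_grid`.
#' @param n number of placements.
#' @param zone placement zone.
#' @param section restrict to one section (overrides `zone`).
#' @param lot_band_start,perisomatic_max zone boundaries (um).
#' @return list of [dendritic_location()]s.
#' @export
sample_locations <- function(grid, n, zone = "apical", section = NULL,
                             lot_band_start = 250, perisomatic_max = 100) {
  cc <- grid$comps[!is.na(grid$comps$parent_comp), ]
  if (!is.null(section)) {
    cc <- cc[cc$section %in% section, ]
  } else if (zone != "apical") {
    z <- ifelse(cc$path_dist <= perisomatic_max, "perisomatic",
                ifelse(cc$path_dist >= lot_band_start, "LOT", "IC"))
    cc <- cc[z == zone, ]
  }
  if (nrow(cc) == 0) abort("no compartments available in the requested zone",
                           class = "pir_placement_error")
  idx <- sample.int(nrow(cc), n, replace = TRUE, prob = cc$area)
  lapply(idx, function(i) {
    dendritic_location(cc$section[i], runif(1, cc$arc0[i], cc$arc1[i]))
  })
}

#' Build a synapse population tibble
#'
#' One presynaptic cell gives rise to one synapse; an excitatory synapse is
#' an AMPA and an NMDA component at the same location sharing the same
#' vesicle pool and release sequence, an inhibitory synapse a single GABA-A
#' component. The tibble has one row per receptor component.
#'
#' @param locations list of [dendritic_location()]s, one per presynaptic
#'   cell.
#' @param type `"exc"` or `"inh"`.
#' @param nmda include the NMDA component of excitatory synapses (background
#'   excitation is AMPA-only).
#' @param scale multiplicative intensity scale on the unitary conductances
#'   (the calibration knob).
#' @param n_slots,pr,replenish_rate vesicle pool parameters.
#' @param input_prefix prefix for generated input ids.
#' @return tibble with columns `input_id`, `kind`, `section`, `arc`,
#'   `g_unit`, `tau_rise`, `tau_decay`, `e_rev`, `scale`, `n_slots`, `pr`,
#'   `replenish_rate`.
#' @export
synapse_population <- function(locations, type = c("exc", "inh"), nmda = TRUE,
                               scale = 1, n_slots = 5, pr = 0.1,
                               replenish_rate = 100, input_prefix = type) {
  type <- match.arg(type)
  kin <- synapse_kinetics()
  kinds <- if (type == "exc") { if (nmda) c("ampa", "nmda") else "ampa" } else "gabaa"
  rows <- imap(locations, function(loc, i) {
    id <- paste0(input_prefix, "_", i)
    k <- kin[match(kinds, kin$kind), ]
    tibble(input_id = id, kind = k$kind, section = loc$section, arc = loc$arc,
           g_unit = k$g_unit, tau_rise = k$tau_rise, tau_decay = k$tau_decay,
           e_rev = k$e_rev, scale = scale, n_slots = n_slots, pr = pr,
           replenish_rate = replenish_rate)
  })
  bind_rows(rows)
}

#' Export presynaptic trains as a two-column tibble
#'
#' @param trains named list of spike-time vectors.
#' @return tibble with `input_id`, `time` (ms), one row per spike.
#' @export
trains_to_table <- function(trains) {
  bind_rows(imap(trains, function(tt, id) {
    if (length(tt) == 0) return(NULL)
    tibble(input_id = id, time = tt)
  }))
}
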