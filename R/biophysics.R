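#' Passive membrane parameters
#'
#' Defaults are the model cell's values: specific membrane resistance
#' 25,000 ohm cm^2, axial resistivity 100 ohm cm, specific capacitance
#' 1 uF/cm^2, resting potential -70 mV (membrane time constant 25 ms).
#'
#' @param Rm specific membrane resistance, ohm cm^2.
#' @param Ra axial resistivity, ohm cm.
#' @param Cm specific membrane capacitance, uF/cm^2.
#' @param E_rest resting potential, mV.
#' @export
passive_params <- function(Rm = 25000, Ra = 100, Cm = 1, E_rest = -70) {
  stopifnot(Rm > 0, Ra > 0, Cm >= 0)
  structure(list(Rm = Rm, Ra = Ra, Cm = Cm, E_rest = E_rest),
            class = "pir_passive")
}

#' Passive membrane time constant (ms)
#'
#' `tau = Rm * Cm`: ohm cm^2 times uF/cm^2 gives microseconds times 1000,
#' i.e. `Rm * Cm / 1000` ms (25 ms at the defaults).
#'
#' @param p a [passive_params()].
#' @export
passive_time_constant <- function(p) {
  p$Rm * p$Cm * 1e-3
}

#' Voltage-gated channel set
#'
#' Hodgkin-Huxley style fast sodium (m^3 h), delayed-rectifier potassium
#' (n^4) and a slow non-inactivating potassium conductance for spike
#' generation and adaptation. Default densities are the model's printed
#' values (gNa 1000, gKdr 500, gKs 20 mS/cm^2; ENa +50, EK -87 mV).
#'
#' The rate functions are threshold-shifted Traub-type kinetics with spike
#' threshold parameter `VT` (default -55 mV) so that rest at -70 mV is
#' stable despite the large densities. The slow potassium conductance is an
#' M-like first-order activation with half-activation `ks_vhalf`, slope
#' `ks_slope`, and a bell-shaped time constant scaled so that it equals
#' `ks_tau_rest` (default 100 ms) at -70 mV; its half-activation defaults to
#' -10 mV so that it accumulates during spiking (adaptation) without
#' dominating subthreshold integration.
#'
#' @param gNa,gKdr,gKs conductance densities, mS/cm^2.
#' @param ENa,EK reversal potentials, mV.
#' @param placement `"soma"` (default), `"all"`, or an integer vector of
#'   compartment indices.
#' @param VT spike-threshold shift for the Na/Kdr rate functions, mV.
#' @param ks_vhalf,ks_slope slow-K activation curve parameters, mV.
#' @param ks_tau_rest slow-K activation time constant at -70 mV, ms.
#' @export
channel_set <- function(gNa = 1000, ENa = 50, gKdr = 500, gKs = 20, EK = -87,
                        placement = "soma", VT = -55,
                        ks_vhalf = -10, ks_slope = 10, ks_tau_rest = 100) {
  stopifnot(gNa >= 0, gKdr >= 0, gKs >= 0, is.finite(ENa), is.finite(EK))
  x <- (-70 - ks_vhalf) / 20
  taumax <- ks_tau_rest * (3.3 * exp(x) + exp(-x))
  structure(list(gNa = gNa, ENa = ENa, gKdr = gKdr, gKs = gKs, EK = EK,
                 placement = placement, VT = VT, ks_vhalf = ks_vhalf,
                 ks_slope = ks_slope, ks_taumax = taumax),
            class = "pir_channels")
}

#' NMDA receptor conductance voltage dependence
#'
#' The magnesium-block gating factor `1 / (1 + 0.25 * exp(-0.08 * Vm))`,
#' a dimensionless fraction in (0, 1), strictly increasing in `Vm`.
#'
#' @param Vm membrane potential, mV (vectorised).
#' @export
nmda_gating <- function(Vm) {
  1 / (1 + 0.25 * exp(-0.08 * Vm))
}

# HH rate functions (ms^-1) used by both the R reference implementation and
# the compiled engine (duplicated there for speed)
hh_rate_fns <- function(v, VT) {
  vtrap <- function(x, y) ifelse(abs(x / y) < 1e-6, y * (1 - x / y / 2),
                                 x / (exp(x / y) - 1))
  u <- v - VT
  list(
    am = 0.32 * vtrap(13 - u, 4),
    bm = 0.28 * vtrap(u - 40, 5),
    ah = 0.128 * exp(-(u - 17) / 18),
    bh = 4 / (1 + exp(-(u - 40) / 5)),
    an = 0.032 * vtrap(15 - u, 5),
    bn = 0.5 * exp(-(u - 10) / 40)
  )
}

ks_kinetics <- function(v, ch) {
  x <- (v - ch$ks_vhalf) / 20
  list(pinf = 1 / (1 + exp(-(v - ch$ks_vhalf) / ch$ks_slope)),
       ptau = ch$ks_taumax / (3.3 * exp(x) + exp(-x)))
}

#' Steady-state gating variables at a holding voltage
#'
#' @param Vm membrane potential, mV.
#' @param channels a [channel_set()].
#' @return named list with `m`, `h`, `n`, `p` in `[0, 1]`.
#' @export
steady_gating <- function(Vm, channels) {
  r <- hh_rate_fns(Vm, channels$VT)
  ks <- ks_kinetics(Vm, channels)
  list(m = r$am / (r$am + r$bm), h = r$ah / (r$ah + r$bh),
       n = r$an / (r$an + r$bn), p = ks$pinf)
}

#' One step of channel gating and ionic current (reference implementation)
#'
#' Advances the gating variables by `dt` at fixed `Vm` (exponential update
#' against their voltage-dependent steady states) and returns the ionic
#' current density. This R implementation mirrors the compiled engine and is
#' used for analytic checks; densities are in mS/cm^2 and the current in
#' uA/cm^2 (positive outward).
#'
#' @param state named list with gating variables `m`, `h`, `n`, `p`, each in
#'   `[0, 1]` (see [steady_gating()]).
#' @param Vm membrane potential, mV.
#' @param channels a [channel_set()].
#' @param dt time step, ms.
#' @return list with `current` (uA/cm^2) and the updated `state`.
#' @export
channel_currents <- function(state, Vm, channels, dt) {
  stopifnot(all(unlist(state[c("m", "h", "n", "p")]) >= 0),
            all(unlist(state[c("m", "h", "n", "p")]) <= 1))
  r <- hh_rate_fns(Vm, channels$VT)
  ks <- ks_kinetics(Vm, channels)
  upd <- function(x, xinf, tau) x + (xinf - x) * (1 - exp(-dt / tau))
  st <- list(
    m = upd(state$m, r$am / (r$am + r$bm), 1 / (r$am + r$bm)),
    h = upd(state$h, r$ah / (r$ah + r$bh), 1 / (r$ah + r$bh)),
    n = upd(state$n, r$an / (r$an + r$bn), 1 / (r$an + r$bn)),
    p = upd(state$p, ks$pinf, ks$ptau)
  )
  i <- channels$gNa * st$m^3 * st$h * (Vm - channels$ENa) +
    channels$gKdr * st$n^4 * (Vm - channels$EK) +
    channels$gKs * st$p * (Vm - channels$EK)
  # mS/cm^2 * mV = uA/cm^2
  list(current = i, state = st)
}
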