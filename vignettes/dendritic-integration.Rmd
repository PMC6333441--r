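---
title: "Modelling NMDA-spike integration in piriform cortex pyramidal neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling NMDA-spike integration in piriform cortex pyramidal neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`piriform` simulates synaptic integration in the apical dendritic tree of an
olfactory-cortex pyramidal neuron, with local NMDA-receptor-mediated spikes
as the central nonlinearity. This vignette is the package's account of the
model: its equations and assumptions, the parameters that matter, what the
synthetic data emulate (and what they do not), the numerical choices, and
the design decisions taken where the problem was genuinely open.

## The model

The cell is a rooted tree of cylindrical sections — a soma cylinder plus an
apical arbor — discretized into iso-potential compartments of at most a few
micrometres (`discretize()`, default 4.6 µm, hard cap 19 µm). Each
compartment obeys the cable equation

$$C_i \frac{dV_i}{dt} = -g_{L,i}(V_i - E_L) - I^{chan}_i - I^{syn}_i +
\sum_{j \in \mathcal{N}(i)} g_{ij}(V_j - V_i) + I^{inj}_i,$$

with specific membrane resistance 25,000 Ω·cm², axial resistivity
100 Ω·cm, capacitance 1 µF/cm², and resting potential −70 mV, giving a
25 ms membrane time constant. Axial conductances couple compartment centres
through frusta of the tapered sections.

**Synapses.** An excitatory synapse carries colocalised AMPA
(instantaneous rise, 1.5 ms decay, 1 nS, reversal 0 mV) and NMDA (2 ms
rise, 80 ms decay, 2 nS) conductances; inhibition is GABA-A (instantaneous
rise, 7 ms decay, 2 nS, reversal −70 mV). The NMDA conductance is
multiplied by the magnesium-block factor
$g(V) = 1/(1 + 0.25\,e^{-0.08V})$, which rises e-fold per 12.5 mV — the
source of all regenerative behaviour in the model. The "Ohmic NMDA"
control (`set_ohmic_nmda()`) evaluates this factor at a fixed −70 mV for
the whole run, which linearises the synapse while preserving its kinetics.

**Release.** Each presynaptic cell makes exactly one synapse holding five
vesicles; at each presynaptic spike every available vesicle is released
independently with probability 0.1, and empty slots refill with memoryless
kinetics at 100 s⁻¹. Release depends only on the presynaptic train, so the
whole release sequence is drawn before integration, one independent RNG
substream per input — results do not depend on synapse iteration order.

**Unitary conductance convention.** The published unitary values are stated
as *average* conductances. With a five-vesicle pool at release probability
0.1, the average release event is half a vesicle, so the package reads the
printed numbers as event means: per-vesicle conductance is
`g_unit / (n_slots × Pr)` (`unitary_meaning = "event_mean"`). Two
alternative readings — full-pool (`g_unit/n_slots` per vesicle) and
per-vesicle — are config switches, with an independent switch for GABA-A
(`gaba_meaning`). The event-mean reading is the only one we found
consistent with the reported ~11 mV background depolarization: the
full-pool reading yields only 2–3 mV from the same population. Applied
uniformly to inhibition it also turns out to be what suppresses the
dendritic recruitment of dispersed excitation (below).

**Channels.** Na⁺/K⁺ conductances use threshold-shifted Traub-type rate
functions (spike-threshold parameter VT = −55 mV) so that rest at −70 mV is
stable despite the large published densities; the slow non-inactivating K⁺
conductance is M-like with half-activation −10 mV, slope 10 mV, and a
bell-shaped time constant scaled to 100 ms at −70 mV, so it accumulates
across spikes (adaptation) without dominating subthreshold integration.
The exact rate functions were an open choice; these are standard cortical
kinetics. A constant per-compartment bias current computed at rest keeps
−70 mV an exact steady state after channel insertion.

By default, protocol-level systems are built *without* voltage-gated
channels: every quantity the protocols measure is a subthreshold EPSP, and
at the published density the slow K⁺ conductance would otherwise shunt the
background depolarization. Somatic channels are one configuration key away
(`channels = "soma"`), and the adaptation behaviour is exercised in the
test suite.

## The synthetic morphology

No reconstructed morphology is published, so `generate_synthetic_morphology()`
builds a stand-in constrained by the stated summary statistics: an
829 µm² soma (a cylinder with length = diameter = 16.24 µm), total
dendritic length drawn uniformly in [2238, 2516] µm, and roughly 500
compartments at the default segment length. The shape parameters —
unconstrained by those summaries — were calibrated once, during model
development, against the *operating points* the original modelling work
demonstrably sat at, and then frozen:

* three primary apical dendrites with binary branching to depth four
  (section length means 200/160/55/25 µm, CV 0.15), giving 24 short
  terminal branches and tips beyond 360 µm;
* branch-order diameters 2.8/2.2/2.0/1.8 µm, each section tapering to the
  next order's calibre.

The operating points used for that calibration: a single calibrated input
produces a ~30 pA somatic EPSC and an EPSP inside the reported band; the
background population depolarizes the soma by an amount inside the reported
band; a six-input glomerulus is subthreshold on its own while twelve inputs
on one branch reliably ignite an NMDA spike; and dispersed excitation fails
to ignite any branch. On this geometry the local-spike threshold at a
distal terminal is ~7 co-active calibrated inputs and the corresponding
somatic "threshold voltage" falls in the experimentally observed 10–20 mV
range. All shape parameters remain user-configurable, and user-supplied
SWC morphologies can be substituted (`read_swc()`).

What the generator does *not* emulate: basal dendrites and the axon (the
analysis concerns the apical tree), spines, continuous natural taper,
reconstruction noise, and the between-cell variability of real
morphologies. Passing tests therefore show that the *mechanisms* behave
correctly on a plausible apical tree, not that any real cell's numbers are
point-reproduced.

## Stimulation protocols

* `calibrate_unitary_input()` scales a single distal excitatory synapse so
  its mean somatic voltage-clamp EPSC magnitude (over ≥100 single-spike
  release trials, failures included) matches 30 pA, then reports the mean
  current-clamp EPSP.
* `io_curve()` delivers a burst (3 pulses, 50 Hz) through 0…n calibrated
  synapses spread within a 30 µm focal footprint at a site and measures
  somatic and local peak/area above baseline. "Intensity" is the number of
  co-active synapses — the model analogue of stimulation strength.
* `detect_threshold()` fits a four-parameter logistic (self-starting,
  with a bounded fallback fit) to peak-vs-intensity and compares it with a
  straight line by AIC; the threshold intensity is the fitted inflection,
  the threshold voltage the mean peak at the largest intensity below it.
  If the line wins (or the fitted sigmoid is degenerate) no spike is
  reported.
* `pairing_experiment()` measures how a constant subthreshold bias input
  (default ~3 synapses, somatic EPSP of a few millivolts, matching the
  experimental bias) shifts the driver's curve; `select_pairing_sites()`
  places driver and bias on the same branch, a sister branch (same primary
  dendrite, maximally separated subtree), or a different primary, with LOT
  biases distal and IC biases at ~240 µm. The bias burst can be
  time-shifted.
* `clustered_vs_dispersed()` and `glomerular_combination()` are the
  in-vivo-like protocols: mitral-cell-like trains (start 100 ± 6 ms,
  ISI 8 ± 5 ms, 5 ± 3 spikes; inhibition 110 ± 6 ms, 10 ± 3 spikes), a
  120-input background population (100 AMPA-only excitatory + 20
  inhibitory Poisson inputs at 10 Hz), feedforward/feedback inhibition
  split 50/50 between the distal LOT band and the perisomatic region, and
  matched presynaptic trains across the conditions being compared.

`background_depolarization()` measures the mean somatic depolarization
produced by the background population alone, discarding the first 150 ms
(six membrane time constants).

## Statistics

`peak_and_area()` uses a 50 ms pre-stimulus baseline and a response window
of stimulus onset + 300 ms for burst protocols (three NMDA decay constants
plus the burst); train protocols run 500 ms so the window captures the NMDA
tail. `pairing_nonlinearity()` is the ratio of the background-subtracted
area under the paired response to the area under the expected linear sum of
the single responses; 1 is linear. Ratios whose expected-linear area is
near zero or negative are excluded and counted rather than clipped
(`min_expected_auc`, 50 mV·ms in the glomerular protocol) — with strong
trial-to-trial variability the denominator occasionally collapses and
would otherwise produce unbounded ratio artifacts. `threshold_reduction()`
is `100·(θ_unpaired − θ_paired)/θ_unpaired` on threshold intensities.

## Numerical choices

* **Integration**: theta-rule with θ = 0.5 (Crank–Nicolson) and a
  Hines-ordered direct tree solve (one elimination sweep leaves-to-root,
  one substitution sweep back), unconditionally stable on the stiff coupled
  system. Default dt = 0.025 ms; halving dt changes the peak somatic
  response to the standard synaptic stimulus by well under 0.5% (tested).
* **Staggering**: synaptic kinetic states advance analytically; the NMDA
  gating factor and HH gating variables are evaluated against the previous
  step's voltage, preserving the linear solve. The gating factor changes
  slowly relative to dt.
* **Release events** snap to the nearest time step; releases with zero
  vesicles are dropped.
* **Voltage clamp** replaces the clamped node's equation and reports the
  electrode current from the post-solve neighbour voltages; inward synaptic
  current appears as negative electrode current.
* **Degenerate inputs**: zero-intensity stimuli produce identically flat
  responses; empty trains are allowed everywhere; a bias that is
  suprathreshold on its own is a protocol error, as is a clustered pool
  exceeding ~2 synapses per µm of target branch.
* **Mean-field release for threshold mapping**: input–output curves used
  for threshold extraction in the tests replace binomial sampling by its
  expectation (`deterministic_release = TRUE`). With five vesicles at
  Pr = 0.1 the per-event conductance CV is ~1.3, and at the handful of
  trials per intensity affordable in a test run the mean curves are
  non-monotone and the logistic fit unstable; the original analyses used
  hundreds of repetitions per intensity. Stochastic release remains the
  default for all other protocols and is itself validated against binomial
  oracles.

## Problem sizes in the tests

The test suite runs the full acceptance battery at desk scale, chosen to
keep the suite in the tens of minutes: 20 background trials of 600 ms at
dt = 0.025 ms; 100 calibration trials; 30 matched trials per
clustered/dispersed arm and 24 glomerular trials at dt = 0.05 ms; and the
pairing/gradient/time-shift properties across 20 independently generated
morphologies with mean-field release. The original analyses used 100–1000
repetitions per condition; the assertions here are correspondingly about
orderings and bands, not point values.

## Known limitations

* The background depolarization of the default cell sits in the lower half
  of the reported 11.2 ± 2.3 mV band (~9–10 mV across seeds): the membrane
  area needed to keep single glomeruli subthreshold, together with the
  uniform event-mean reading of the inhibitory conductance, pulls the mean
  down. Within the published passive parameters we did not find a geometry
  that centres the band *and* preserves the selectivity regime.
* Between-branch compartmentalization is qualitatively right but weaker
  than in the experiments: a different-branch bias still reduces the
  driver's threshold by roughly a third of the same-branch effect, versus
  about one-tenth experimentally. Real trees are larger and more
  asymmetric, and their distal branches far more numerous, than the
  synthetic stand-in.
* The model contains no calcium dynamics, no synaptic plasticity, no
  dendritic Na⁺/K⁺ channels by default, and reads out subthreshold somatic
  EPSPs only; somatic action-potential-based readouts and network effects
  are out of scope.
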