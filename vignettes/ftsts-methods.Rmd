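---
title: "Model and methods: seizure network simulation and FTSTS protocol design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: seizure network simulation and FTSTS protocol design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ftsts)
```

# The scientific problem

Epileptic seizures are episodes of pathologically synchronized firing.
Stimulation therapies that merely suppress firing during the ictal period do
not change the synaptic substrate that generates seizures, so seizures
return when the stimulation stops. Forced Temporal Spike-Time Stimulation
(FTSTS) takes the opposite approach: paired charge-balanced biphasic pulse
trains are delivered to the excitatory and the inhibitory population so that
the two populations are forced to fire in a chosen temporal order. Because
excitatory-to-inhibitory (E-to-I) synapses are plastic under Hebbian
spike-timing-dependent plasticity (STDP), forcing presynaptic-before-
postsynaptic order strengthens E-to-I coupling (more feed-forward
inhibition, fewer future seizures) and the reverse order weakens it. The
package simulates a neocortical-onset seizure network, implements the
electrical and optogenetic FTSTS protocol families, and measures protocol
efficacy as the rate of change of the average E-to-I synaptic weight.

# The network model

Two populations of `N_E = 500` excitatory and `N_I = 500` inhibitory
stochastic conductance-based integrate-and-fire neurons sit on a
one-dimensional line. The membrane potential obeys

$$C\,\dot V = g_L(E_L - V) + f_{max}\,[\,g_E(E_E - V) + g_I(E_{Cl} - V)
  + g_K(E_K - V)\,] + I_{app},$$

in the unit system {mV, nS, pF, pA, ms, mM}, in which no conversion factors
are needed (nS·mV = pA, pA/pF = mV/ms). Spikes are an inhomogeneous Poisson
process with instantaneous rate $f = f_0 e^{(V-\phi)/\beta}$; the per-step
spike probability uses the exact thinning form $p = 1 - e^{-f\,dt}$. A
spiking neuron's potential is painted to $(40 + V)/2$ for the spike step
(the action-potential excursion, which the chloride flux of that step sees)
and is reset to $V_{pre} - 20$ mV at the next step — a hyperpolarizing
reset 20 mV below the pre-spike potential. The firing threshold $\phi$
relaxes to $\phi_0$ with $\tau_\phi = 100$ ms and jumps by $\Delta_\phi$ at
each spike (spike-triggered threshold adaptation). A slow
after-hyperpolarization (sAHP) conductance $g_K$ decays with
$\tau_K = 5$ s and receives $\Delta_K/\tau_K$ per spike.

The GABA reversal potential is not fixed: it follows the intracellular
chloride concentration through the Nernst relation
$E_{Cl} = -26.7\,\ln([Cl]_{out}/[Cl]_{in})$ (−77.7 mV at the 6/110 mM
equilibrium). Chloride is loaded by the GABAergic current
$I_{Cl} = g_I (V - E_{Cl})$ — an outward positive current is an inward
anion flux — and relaxes to equilibrium with $\tau_{Cl} = 5$ s:

$$\frac{d[Cl]_{in}}{dt} = \frac{I_{Cl}}{V_d F}
  - \frac{[Cl]_{in} - [Cl]_{in,eq}}{\tau_{Cl}}.$$

This is the engine of seizure maintenance: sustained inhibition during
intense firing loads chloride, $E_{Cl}$ climbs toward and past $V$, GABA
loses (and finally inverts) its effect, and the discharge becomes
self-sustaining.

Connectivity is distance-dependent and deterministic: neurons occupy
normalized positions $x_k = k/N$ on the unit line; each projection kernel is
the Gaussian pdf of width $\sigma_E = 0.02$ (excitatory) or
$\sigma_I = 0.03$ (inhibitory) in the same normalized units; each
presynaptic row is normalized to one and scaled by the row budget
(104/100/250/250 nS for E→E/E→I/I→I/I→E), and inhibitory projections carry
a weak uniform component $W^{UI}/N = 0.1$ nS per synapse. The line is open;
row normalization absorbs edge truncation, so row sums are exact.

# Plasticity and the efficacy readout

E→E and E→I synapses carry multiplicative plastic fractions $W^p$
(initially 1, clamped at 0 from below, unbounded above). Every neuron has
one eligibility trace that decays with $\tau_{STDP} = 15$ ms and jumps by
$A_0$ at its own spikes (all-to-all accumulation). A presynaptic spike
depresses its row by $\eta A_{post}$; a postsynaptic spike potentiates its
column by $\eta A_{pre}$; $\eta = 10^{-3}$. Updates use the traces as they
stood before the current step's increments, so exactly coincident pre/post
spikes do not interact — an explicit tie-break that makes the update order
independent.

The efficacy readout is the average E-to-I synaptic weight: the mean over
inhibitory neurons of their summed effective incoming weight
$\sum_i \bar W^{EI}_{ij} W^{p,EI}_{ij}$. With all fractions at 1 this is
exactly the 100 nS row budget, and ±15–30 nS excursions are the scale on
which protocols act. A protocol's efficacy is the change in this quantity
across the stimulation window divided by the window length (nS/s).

# The FTSTS waveforms

One biphasic pulse is two contiguous square phases of width $W$ and
amplitude $A$; pulse pairs repeat every $2W + T$ ms ($T$ = inter-pulse
interval; $W=1$, $T=10$ → 12 ms cycle ≈ 83 Hz). Polarity +1 begins with the
negative phase, −1 with the positive phase. The four protocols are the four
polarity pairings $(a_E, a_I)$: standard (+1,−1), inverted-standard
(−1,+1), mirrored (+1,+1), inverted-mirrored (−1,−1). The train-offset
$\Delta\phi$ shifts the phase of the inhibitory train's pattern inside the
common stimulation window; implementing the offset as a cyclic phase shift
makes offsets differing by a whole cycle bit-identical, at the cost of at
most one pulse pair at the window edges relative to a literal start-time
shift. Only complete pulse pairs are emitted, so every train integrates to
exactly zero charge. Amplitudes are in nA and enter the membrane equation
as current (2 nA for 1 ms on 100 pF slews the potential by 20 mV).

Partial overlap (spatially inseparable populations) is modeled by routing:
a uniformly drawn fraction of each population receives the other
population's train summed in.

# Optogenetic variant

The reduced channelrhodopsin model turns a light flash of intensity
$W_{light}$ into a dimensionless conductance waveform: after a
light-dependent delay, activation saturates toward $A_{act}$ with
$\tau_{act}(W_{light})$ while a two-exponential inactivation settles to the
persistent level $A_{persist} = 1 - A^{(1)}_{inact} - A^{(2)}_{inact}$;
after light-off the waveform decays with $\tau_{off}$ (Chronos 3.6 ms,
Chrimson 15.8 ms). The photocurrent $-g_{ChR2} F (V - V_{ChR2})$ is added
to the membrane equation of every neuron of the expressing population.
Waveforms of successive flashes superpose linearly and are clamped at 1.

The flash geometry is not prescribed by the source material; the package
default is 1 ms flashes at the electrical cadence (12 ms period) with the
blue train leading the red train by 2 ms. To raise the average weight,
Chronos (blue) sits in the excitatory population and Chrimson (red) in the
inhibitory population; to lower it the opsins are swapped — the fast opsin
must sit in the population required to fire first, because Chrimson's slow
closure smears its population's spike times late.

# Parameter provenance and calibration

Most constants are taken directly from the published neocortical seizure
model parameter table. Four points required interpretation, resolved once
and frozen:

* **Threshold increment $\Delta_\phi$.** The printed value (−55 mV,
  duplicating $\phi_0$) cannot be an increment: a negative jump after every
  spike produces runaway excitation. It is treated as a signed calibration
  parameter (below).
* **Chloride equation sign.** As printed, both terms of the chloride ODE
  are anti-restoring (activity would *unload* chloride and the equilibrium
  would repel). The implementation uses the physically consistent overall
  sign, which restores the 6 mM equilibrium and loads chloride during
  inhibition, as the described seizure mechanism requires.
* **Synaptic increment normalization.** Adding the raw weight $W(i,j)$ to
  the conductance per spike gives ~5 mV single-spike somatic deflections
  through the strongest synapses; the spontaneous avalanche branching ratio
  then exceeds one and the resting network seizes within hundreds of
  milliseconds with no input. Deliveries are therefore impulse-normalized —
  one spike adds $s\,W/\tau_{syn}$, mirroring the table's own sAHP
  increment $\Delta_K/\tau_K$ — with a single dimensionless efficacy gain
  $s$ (`syn_gain`).
* **$f_{max}$** is the dimensionless per-ms factor 0.2 scaling the
  conductances, exactly as the membrane equation is written; it is not
  applied to the chloride current and does not cap the sampled rate (a
  `cap_rate` flag exists).

The two free parameters ($\Delta_\phi$, `syn_gain`) were calibrated jointly
against the qualitative behaviour the seizure model is defined by, and
nothing else: (i) the unstimulated network is quiescent (~0.5 Hz/neuron)
for at least tens of seconds; (ii) the standard seizure-initiating input
(200 pA for 3 s into the central 50 excitatory neurons) triggers a
discharge that propagates and *outlasts* the input; (iii) the seizure
self-terminates after tens of seconds through threshold adaptation and
sAHP; (iv) interictal activity returns to baseline as chloride re-
equilibrates; and (v) on some seeds ictal activity re-emerges
spontaneously. The frozen defaults are $\Delta_\phi = +3.5$ mV and
`syn_gain = 5`. At this point the network is bistable in exactly the sense
the seizure model requires: single spontaneous spikes do not ignite it, but
the focal input drives local chloride loading that flips GABA from
restraining to permissive and leaves a self-sustained ictal state behind.

# Numerical choices

Forward Euler with $dt = 0.5$ ms throughout; all waveform times (widths,
intervals, offsets, windows) must be integer multiples of $dt$ so that
waveforms are bit-exact. One uniform variate is drawn per neuron per step
from R's global stream, excitatory population first in ascending index;
routing subsets are drawn before the main loop. Everything downstream of
`set.seed()` is therefore bit-reproducible, and the compiled main loop
(Rcpp) reproduces the pure-R reference loop — built from the exported
module operations — bit for bit, which the test-suite asserts. The spike
probability exponent is clamped at $z = 60$ so saturation, not overflow,
handles extreme drives. Chloride must stay positive; a non-positive value
aborts the run with the step index (it signals unit misconfiguration).
Weight snapshots default to a 100 ms cadence, and stimulation-window
endpoints must land on that grid.

# What the simulations do and do not show

The synthetic experiment reproduces the study conditions: the 500E+500I
network, the published constants, seizure induction at 1 s, stimulation at
10 s, efficacy measured over the 5 s stimulation window and averaged over
seeds. Within those conditions the package reproduces the qualitative
structure of the published results: the sign of the weight change for all
four polarities at their best offsets, the immediate termination of the
ongoing seizure by the inverted-standard protocol and the persistence of
ictal activity under the standard protocol, the decay of efficacy with
stimulation overlap, and bidirectional optogenetic control with the 40 s
decrease variant crossing the 15 nS mark.

Quantitative efficacy magnitudes fall short of the printed best-parameter
rates for several conditions (measured here at roughly 0.1–1.6 times the
printed values depending on the row, with both under- and overshoots).
Two mechanisms identified during development plausibly account for this.
First, a charge-balanced biphasic pulse of polarity +1 (negative phase
first) is self-cancelling on a passive membrane, so from near rest it
cannot force a spike; the inhibitory population's forced volley is
correspondingly softer, and part of its firing is driven by the excitatory
volley through E→I synapses smeared across the whole pulse cycle, which
cancels much of the intended pairing asymmetry. Second, with $dt = 0.5$ ms
many forced pre/post pairs land on the same step and contribute nothing
under the documented coincidence tie-break. Both are consequences of
reconstruction choices the source material leaves open; they are recorded
here rather than compensated by re-tuning plasticity constants. Spontaneous
seizure re-emergence after a long quiet interictal period is the least
robust feature: most seeds produce one waxing-and-waning seizure complex
followed by lasting quiescence.

The model also inherits the published model's simplifications: no synaptic
transmission delays, single-compartment neurons, deterministic
connectivity, population-wide uniform stimulation fields, and no
light-scattering or spectral-overlap modeling for the optogenetic variant.

# Problem sizes used by the test-suite

Module tests run on 10–20-neuron lines with widened kernels; engine
equivalence (R reference vs compiled core) runs 800 steps on a 15+15
network. The reproduction suite runs the full 500+500 network: five seeds
per electrical condition over 15.1 s of simulated time, three seeds per
optogenetic direction (20.1 s and 50.1 s), one 150 s untreated run and two
60 s treated runs. `scripts/acceptance.R` repeats the electrical and
optogenetic conditions from scratch at the same sizes.
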