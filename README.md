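# ftsts

Spiking-network simulation of neocortical-onset seizures and the Forced
Temporal Spike-Time Stimulation (FTSTS) protocol family.

## The problem

Stimulation therapies for drug-resistant epilepsy suppress synchronized
firing while they are on, but the synaptic wiring that generates seizures is
untouched, so seizures return. FTSTS instead *re-wires* the network: paired
charge-balanced biphasic pulse trains are delivered to the excitatory (E)
and inhibitory (I) populations so that the two populations fire in a forced
temporal order. Under Hebbian spike-timing-dependent plasticity (STDP),
forcing E-before-I firing potentiates E→I synapses (more feed-forward
inhibition, fewer seizures); the reverse order depresses them. This package
is for computational neuroscientists and neurostimulation engineers who
want to simulate those protocols and optimize their parameters.

The simulator implements:

* a 500E + 500I conductance-based stochastic integrate-and-fire network on
  a line, with adaptive firing thresholds
  (`f = f0 exp((V - phi)/beta)`), slow after-hyperpolarization, and a
  chloride-dependent GABA reversal
  (`E_Cl = -26.7 ln([Cl]_out/[Cl]_in)`) — intense inhibition loads
  chloride, collapses `E_Cl`, and makes the seizure self-sustaining;
* distance-dependent Gaussian connectivity with exact per-row weight
  budgets (104/100/250/250 nS) and trace-based all-to-all STDP on the E→E
  and E→I projections (`eta = 1e-3`, `tau_STDP = 15` ms);
* the four FTSTS polarity pairings (standard, inverted-standard, mirrored,
  inverted-mirrored), pulse amplitude/width/frequency/train-offset control,
  partial E/I stimulation overlap, and an optogenetic variant built on
  reduced Chronos and Chrimson photocurrent models;
* parameter sweeps with seed averaging, scored by the rate of change of
  the average E→I synaptic weight (nS/s) over the stimulation window.

## A worked example

Induce a seizure (200 pA for 3 s into 50 central excitatory neurons at
t = 1 s), then apply the optimal weight-increasing protocol — the
inverted-standard polarity pair (a_E = −1, a_I = +1) at 2 nA, 1 ms pulse
width, 83 Hz, train-offset −0.5 ms — for 5 s starting at t = 10 s:

```r
library(ftsts)
proto <- ftsts_protocol("inverted-standard", amplitude = 2, width = 1,
                        inter_pulse_interval = 10, train_offset = -0.5,
                        onset = 10000, duration = 5000)
cfg <- simulation_config(duration = 15100, seed = 1, protocols = proto)
sim <- run_simulation(cfg)
sim
#> FTSTS seizure-network simulation
#>   populations : 500 excitatory + 500 inhibitory
#>   duration    : 15.1 s at dt = 0.5 ms (seed 1)
#>   seizure     : 200 pA to 50 neurons, t = 1.0-4.0 s
#>   protocol    : inverted-standard (a_E=-1, a_I=+1), 2 nA, W=1 ms, T=10 ms, offset -0.5 ms, t = 10.0-15.0 s
#>   spikes      : 542599 recorded
#>   avg E-to-I  : 100.00 nS initial, 123.84 nS final
efficacy_rate(sim, c(10000, 15000))
#> [1] 4.70876
```

The efficacy, +4.71 nS/s, is the rise of the average E→I synaptic weight
per second of stimulation: starting from the 100 nS baseline (the E→I row
budget), 5 s of stimulation raised the mean total excitatory drive onto
each inhibitory neuron by ~24 nS, which in this run terminates the ongoing
seizure at the end of the stimulation window. `plot(sim)` draws the spike
raster and the weight trace. Swapping to `train_offset = -2` reverses the
sign of the effect (post-before-pre forcing), and `run_sweep()` maps the
full amplitude x offset x width x frequency x polarity surface:

```r
base <- simulation_config(duration = 15100, seed = 1,
                          protocols = ftsts_protocol("inverted-standard"),
                          record_raster = FALSE)
sw <- run_sweep(sweep_spec(train_offset = seq(-3, 3, 0.5), seeds = 1:5,
                           base_config = base))
export_report(sw, "sweep-out")
```

Command-line wrappers live in `inst/scripts/` (`ftsts-simulate.R`,
`ftsts-sweep.R`).

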