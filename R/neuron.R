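#' Initialize a population state
#'
#' All neurons start at the leak reversal, baseline threshold, zero
#' conductances and equilibrium chloride; `t_last_spike` is set to `-Inf` so
#' no neuron starts refractory.
#'
#' @param n population size.
#' @param params a [neuron_params()] object.
#' @return A list of class `"ftsts_state"` with per-neuron vectors `V`, `phi`,
#'   `g_E`, `g_I`, `g_K`, `Cl_in`, `E_Cl`, `t_last_spike`, plus bookkeeping
#'   for the two-step spike reset (`spiked`, `V_spike`).
#' @export
init_state <- function(n, params) {
  E_Cl <- nernst_potential(params$Cl_in_eq, params)
  structure(list(V = rep(params$E_L, n), phi = rep(params$phi0, n),
                 g_E = numeric(n), g_I = numeric(n), g_K = numeric(n),
                 Cl_in = rep(params$Cl_in_eq, n), E_Cl = rep(E_Cl, n),
                 t_last_spike = rep(-Inf, n), spiked = logical(n),
                 V_spike = numeric(n)),
            class = "ftsts_state")
}

#' Nernst reversal potential for chloride
#'
#' \eqn{E_{Cl} = -s \,\log([Cl]_{out}/[Cl]_{in})} with slope `s =
#' params$nernst_slope` (mV) and natural log by default (`params$nernst_log`).
#'
#' @param Cl_in intracellular chloride (mM), scalar or vector.
#' @param params a [neuron_params()] object.
#' @return reversal potential(s) in mV.
#' @examples
#' nernst_potential(6, neuron_params())   # ~ -77.7 mV
#' nernst_potential(110, neuron_params()) # 0 mV: no gradient
#' @export
nernst_potential <- function(Cl_in, params) {
  r <- params$Cl_out / Cl_in
  if (identical(params$nernst_log, "base10")) {
    -params$nernst_slope * log10(r)
  } else {
    -params$nernst_slope * log(r)
  }
}

check_state <- function(state, step = NA_integer_) {
  if (any(!is.finite(state$V))) {
    stop("non-finite membrane potential at step ", step, call. = FALSE)
  }
  invisible(state)
}

#' Forward-Euler membrane update
#'
#' One Euler step of the conductance-based membrane equation
#' \deqn{C \frac{dV}{dt} = g_L (E_L - V) + f_{max}\,[g_E (E_E - V) +
#'   g_I (E_{Cl} - V) + g_K (E_K - V)] + I_{app}.}
#' Units: mV, nS, pF, pA, ms.
#'
#' @param state an `ftsts_state`.
#' @param I_app applied current per neuron (pA).
#' @param params a [neuron_params()] object.
#' @param step step index used in error messages.
#' @return the state with `V` advanced by `params$dt`.
#' @export
membrane_step <- function(state, I_app, params, step = NA_integer_) {
  if (length(I_app) != length(state$V)) {
    stop("membrane_step: I_app length does not match population size",
         call. = FALSE)
  }
  dVdt <- (params$g_L * (params$E_L - state$V) +
             params$f_max * (state$g_E * (params$E_E - state$V) +
                               state$g_I * (state$E_Cl - state$V) +
                               state$g_K * (params$E_K - state$V)) +
             I_app) / params$C
  state$V <- state$V + params$dt * dVdt
  check_state(state, step)
  state
}

#' Per-step spike probability
#'
#' Instantaneous rate \eqn{f = f_0 \exp((V-\phi)/\beta)} (Hz) converted to an
#' exact per-step Poisson thinning probability \eqn{p = 1 - e^{-f\,dt}}
#' (with `dt` in ms, `f` internally converted to 1/ms). The exponent is
#' clamped so `p` saturates at 1 instead of overflowing. If
#' `params$cap_rate` is set, `f` is additionally capped at `1000 * f_max` Hz.
#'
#' @param V,phi membrane potential and threshold (mV), vectors.
#' @param params a [neuron_params()] object.
#' @return spike probability per neuron for one step.
#' @export
spike_probability <- function(V, phi, params) {
  z <- pmin((V - phi) / params$beta, 60)
  f <- params$f0 * exp(z)                       # Hz
  if (isTRUE(params$cap_rate)) f <- pmin(f, 1000 * params$f_max)
  -expm1(-f * 1e-3 * params$dt)
}

#' Sample spikes for one step
#'
#' Draws one uniform variate per neuron (ascending index) from the current R
#' random stream and marks neurons whose draw falls below the per-step spike
#' probability, excluding those still refractory
#' (`t - t_last_spike < tau_ref`).
#'
#' @param state an `ftsts_state`.
#' @param params a [neuron_params()] object.
#' @param t current simulation time (ms).
#' @return logical spike mask.
#' @export
sample_spikes <- function(state, params, t) {
  p <- spike_probability(state$V, state$phi, params)
  u <- stats::runif(length(state$V))
  (u < p) & (t - state$t_last_spike >= params$tau_ref)
}

#' Apply the two-step spike reset
#'
#' At the spike step the membrane potential is set to the average of 40 mV
#' and its current value `V(t_i)` (the action-potential excursion, seen by
#' the conductance-driven currents of that step); the threshold jumps by
#' `delta_phi` and `t_last_spike` is updated. At the following step the
#' membrane potential is reset to `V(t_i) - 20` mV — 20 mV below the
#' pre-spike potential, a hyperpolarizing reset — in place of the membrane
#' update; the pending value is recorded in `V_spike`/`spiked` and consumed
#' by [resolve_spike_reset()].
#'
#' @param state an `ftsts_state`.
#' @param spike_mask logical mask from [sample_spikes()].
#' @param params a [neuron_params()] object.
#' @param t current simulation time (ms).
#' @return the updated state.
#' @export
apply_spike_reset <- function(state, spike_mask, params, t) {
  if (any(spike_mask)) {
    state$V_spike[spike_mask] <- state$V[spike_mask]
    state$V[spike_mask] <- (40 + state$V[spike_mask]) / 2
    state$phi[spike_mask] <- state$phi[spike_mask] + params$delta_phi
    state$t_last_spike[spike_mask] <- t
  }
  state$spiked <- spike_mask
  state
}

#' Resolve the pending post-spike reset
#'
#' For neurons that spiked on the previous step, overrides the freshly
#' integrated membrane potential with the stored pre-spike value minus
#' 20 mV.
#'
#' @param state an `ftsts_state`.
#' @return the updated state.
#' @export
resolve_spike_reset <- function(state) {
  if (any(state$spiked)) {
    state$V[state$spiked] <- state$V_spike[state$spiked] - 20
  }
  state
}

#' Threshold relaxation step
#'
#' Euler step of \eqn{\tau_\phi \, d\phi/dt = \phi_0 - \phi}.
#'
#' @param state an `ftsts_state`.
#' @param params a [neuron_params()] object.
#' @return the updated state.
#' @export
threshold_step <- function(state, params) {
  state$phi <- state$phi + params$dt / params$tau_phi * (params$phi0 - state$phi)
  state
}

#' Conductance decay and synaptic delivery
#'
#' `g_E` and `g_I` decay with `tau_syn` and `g_K` with `tau_K` (Euler), then
#' the summed presynaptic effective weights, impulse-normalized by the decay
#' time constant (`weight sum / tau_syn`, so one spike through a weight `W`
#' delivers a total conductance-time integral of `W` nS ms), are added to
#' the postsynaptic conductances. Each neuron that itself spiked receives
#' the sAHP increment `delta_K / tau_K`, normalized the same way.
#'
#' @param state an `ftsts_state`.
#' @param exc_input,inh_input per-neuron summed presynaptic weights (nS)
#'   landing on the glutamatergic and GABAergic conductances.
#' @param own_spikes logical mask of this population's own spikes.
#' @param params a [neuron_params()] object.
#' @return the updated state.
#' @export
conductance_step <- function(state, exc_input, inh_input, own_spikes, params) {
  if (any(exc_input < 0) || any(inh_input < 0)) {
    stop("conductance_step: negative synaptic input", call. = FALSE)
  }
  state$g_E <- state$g_E - params$dt / params$tau_syn * state$g_E +
    params$syn_gain * exc_input / params$tau_syn
  state$g_I <- state$g_I - params$dt / params$tau_syn * state$g_I +
    params$syn_gain * inh_input / params$tau_syn
  state$g_K <- state$g_K - params$dt / params$tau_K * state$g_K
  state$g_K[own_spikes] <- state$g_K[own_spikes] + params$delta_K / params$tau_K
  state
}

#' Chloride dynamics and GABA reversal update
#'
#' The chloride current \eqn{I_{Cl} = g_I (V - E_{Cl})} (pA, outward
#' positive) loads the cell with chloride: since chloride carries charge -1,
#' a positive outward current is an inward anion flux, so
#' \deqn{\frac{d[Cl]_{in}}{dt} = \frac{I_{Cl}}{V_d F}
#'   - \frac{[Cl]_{in} - [Cl]_{in,eq}}{\tau_{Cl}},}
#' which in \{pA, pL, C/mol\} units is directly mM/ms. The reversal potential
#' is then refreshed from the Nernst relation.
#'
#' @param state an `ftsts_state`.
#' @param params a [neuron_params()] object.
#' @param step step index used in error messages.
#' @return the updated state.
#' @export
chloride_step <- function(state, params, step = NA_integer_) {
  I_Cl <- state$g_I * (state$V - state$E_Cl)
  state$Cl_in <- state$Cl_in +
    params$dt * (I_Cl / (params$V_d * params$Faraday) -
                   (state$Cl_in - params$Cl_in_eq) / params$tau_Cl)
  if (any(state$Cl_in <= 0)) {
    stop("chloride_step: non-positive [Cl_in] at step ", step,
         " (check unit configuration)", call. = FALSE)
  }
  state$E_Cl <- nernst_potential(state$Cl_in, params)
  state
}
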