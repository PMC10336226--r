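#' Neuron and network model parameters
#'
#' Constructs the full parameter set of the conductance-based stochastic
#' integrate-and-fire neuron used throughout the simulator. The unit system is
#' fixed to \{mV, nS, pF, pA, ms, mM\}: with these units nS x mV = pA and
#' pA / pF = mV/ms, so the membrane equation needs no conversion factors.
#'
#' Spiking is an inhomogeneous Poisson process with instantaneous rate
#' \eqn{f = f_0 \exp((V - \phi)/\beta)} (Hz). The GABA reversal potential is
#' chloride-dependent through the Nernst relation
#' \eqn{E_{Cl} = -26.7 \ln([Cl]_{out}/[Cl]_{in})} mV.
#'
#' @param C membrane capacitance (pF).
#' @param g_L leak conductance (nS).
#' @param E_L,E_E,E_K leak, glutamatergic and potassium reversal potentials (mV).
#' @param f0 baseline firing rate at threshold (Hz).
#' @param beta softness of the spike threshold (mV).
#' @param tau_ref absolute refractory period (ms).
#' @param tau_syn synaptic conductance decay time constant (ms).
#' @param tau_phi firing-threshold relaxation time constant (ms).
#' @param phi0 baseline firing threshold (mV).
#' @param delta_phi signed post-spike threshold increment (mV). Positive values
#'   give spike-triggered threshold adaptation; the default +3.5 mV is
#'   calibrated jointly with `syn_gain` so that the unstimulated network is
#'   quiescent while the standard focal input triggers a propagating,
#'   self-terminating seizure that can re-emerge spontaneously (see the
#'   methods vignette).
#' @param delta_K numerator of the slow after-hyperpolarization (sAHP)
#'   increment (nS); each spike adds `delta_K / tau_K` to `g_K`.
#' @param f_max dimensionless per-ms rate-scaling factor multiplying the
#'   synaptic and sAHP conductances in the membrane equation (0.2 = inverse of
#'   the 5 ms refractory period).
#' @param V_d volume of distribution of intracellular chloride (pL).
#' @param Faraday Faraday constant (C/mol).
#' @param Cl_in_eq,Cl_out equilibrium intracellular and fixed extracellular
#'   chloride concentrations (mM).
#' @param tau_Cl chloride relaxation time constant (ms).
#' @param tau_K sAHP decay time constant (ms).
#' @param dt integration step of the forward-Euler scheme (ms).
#' @param syn_gain dimensionless synaptic efficacy gain: a presynaptic spike
#'   through weight `W` increments the postsynaptic conductance by
#'   `syn_gain * W / tau_syn`. The default is calibrated (with
#'   `delta_phi`) so the network is bistable: quiescent at rest, yet a focal
#'   depolarizing input leaves a self-sustained chloride-mediated ictal
#'   state behind.
#' @param nernst_slope Nernst slope (mV), ~RT/F at body temperature.
#' @param nernst_log `"natural"` (default) or `"base10"`; log base used in the
#'   Nernst relation.
#' @param cap_rate if `TRUE`, also cap the sampled instantaneous rate at
#'   `1000 * f_max` Hz (off by default: `f_max` only scales conductances).
#'
#' @return A list of class `"ftsts_neuron_params"`.
#' @examples
#' p <- neuron_params()
#' p$C
#' @export
neuron_params <- function(C = 100, g_L = 4, E_L = -57, E_E = 0, E_K = -90,
                          f0 = 2, beta = 1.5, tau_ref = 5, tau_syn = 15,
                          tau_phi = 100, phi0 = -55, delta_phi = 3.5,
                          delta_K = 40, f_max = 0.2, V_d = 0.2357,
                          Faraday = 96500, Cl_in_eq = 6, Cl_out = 110,
                          tau_Cl = 5000, tau_K = 5000, dt = 0.5, syn_gain = 5,
                          nernst_slope = 26.7,
                          nernst_log = c("natural", "base10"),
                          cap_rate = FALSE) {
  nernst_log <- match.arg(nernst_log)
  p <- list(C = C, g_L = g_L, E_L = E_L, E_E = E_E, E_K = E_K, f0 = f0,
            beta = beta, tau_ref = tau_ref, tau_syn = tau_syn,
            tau_phi = tau_phi, phi0 = phi0, delta_phi = delta_phi,
            delta_K = delta_K, f_max = f_max, V_d = V_d, Faraday = Faraday,
            Cl_in_eq = Cl_in_eq, Cl_out = Cl_out, tau_Cl = tau_Cl,
            tau_K = tau_K, dt = dt, syn_gain = syn_gain,
            nernst_slope = nernst_slope,
            nernst_log = nernst_log, cap_rate = cap_rate)
  validate_neuron_params(p)
  class(p) <- "ftsts_neuron_params"
  p
}

validate_neuron_params <- function(p) {
  pos <- c("C", "g_L", "tau_ref", "tau_syn", "tau_phi", "tau_Cl", "tau_K",
           "dt", "V_d", "Faraday", "Cl_in_eq", "Cl_out", "beta", "f0")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("neuron_params: '", nm, "' must be a positive finite scalar",
           call. = FALSE)
    }
  }
  invisible(p)
}

#' Spike-timing-dependent plasticity parameters
#'
#' Trace-based all-to-all Hebbian STDP acting multiplicatively on the E-to-E
#' and E-to-I base weight matrices. Each neuron carries an eligibility trace
#' that decays with `tau_STDP` and jumps by `A0` at its own spikes. A
#' presynaptic spike depresses its row of the plastic fraction by
#' `eta * A_post`; a postsynaptic spike potentiates its column by
#' `eta * A_pre`. Plastic fractions are clamped at zero from below and are
#' unbounded above.
#'
#' @param eta learning rate (dimensionless, per spike event).
#' @param tau_STDP trace time constant (ms); sets the pairing window.
#' @param A0 trace increment per spike (dimensionless).
#' @return A list of class `"ftsts_stdp_params"`.
#' @examples
#' stdp_params()
#' @export
stdp_params <- function(eta = 1e-3, tau_STDP = 15, A0 = 1) {
  if (eta < 0) stop("stdp_params: eta must be >= 0", call. = FALSE)
  if (tau_STDP <= 0) stop("stdp_params: tau_STDP must be > 0", call. = FALSE)
  if (A0 <= 0) stop("stdp_params: A0 must be > 0", call. = FALSE)
  structure(list(eta = eta, tau_STDP = tau_STDP, A0 = A0),
            class = "ftsts_stdp_params")
}

#' Load model parameters from a YAML configuration file
#'
#' Reads a structured configuration whose keys mirror the model parameter
#' names (`C`, `g_L`, `E_L`, ..., `eta`, `tau_STDP`) and returns the
#' corresponding parameter objects. Keys not present fall back to the package
#' defaults. A reference configuration with every default value is shipped at
#' `system.file("extdata", "model_parameters.yaml", package = "ftsts")`.
#'
#' @param path path to a YAML file.
#' @return A list with elements `neuron` (`ftsts_neuron_params`) and
#'   `stdp` (`ftsts_stdp_params`).
#' @export
load_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  nargs <- cfg[intersect(names(cfg), names(formals(neuron_params)))]
  sargs <- cfg[intersect(names(cfg), names(formals(stdp_params)))]
  list(neuron = do.call(neuron_params, nargs),
       stdp = do.call(stdp_params, sargs))
}
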