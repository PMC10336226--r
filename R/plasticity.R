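#' Initialize plastic state
#'
#' Eligibility traces start at zero; the multiplicative plastic fractions on
#' the E-to-E and E-to-I base matrices start at one (i.e., effective weights
#' equal the static matrices).
#'
#' @param N_E,N_I population sizes.
#' @return A list of class `"ftsts_plastic_state"` with trace vectors `A_E`
#'   (one per excitatory neuron, serving as both its presynaptic and
#'   postsynaptic trace) and `A_I`, and plastic fraction matrices `Wp_EE`
#'   (`N_E x N_E`) and `Wp_EI` (`N_E x N_I`).
#' @export
init_plastic_state <- function(N_E, N_I) {
  structure(list(A_E = numeric(N_E), A_I = numeric(N_I),
                 Wp_EE = matrix(1, N_E, N_E), Wp_EI = matrix(1, N_E, N_I)),
            class = "ftsts_plastic_state")
}

#' STDP trace decay and increments
#'
#' Euler decay of all eligibility traces with `tau_STDP`, then a jump of `A0`
#' for every neuron that spiked this step (all-to-all accumulation).
#'
#' @param pstate an `ftsts_plastic_state`.
#' @param spikes_E,spikes_I logical spike masks for the two populations.
#' @param params a [stdp_params()] object.
#' @param dt integration step (ms).
#' @return the updated plastic state.
#' @export
stdp_trace_step <- function(pstate, spikes_E, spikes_I, params, dt) {
  pstate$A_E <- pstate$A_E - dt / params$tau_STDP * pstate$A_E
  pstate$A_I <- pstate$A_I - dt / params$tau_STDP * pstate$A_I
  pstate$A_E[spikes_E] <- pstate$A_E[spikes_E] + params$A0
  pstate$A_I[spikes_I] <- pstate$A_I[spikes_I] + params$A0
  pstate
}

#' STDP weight update
#'
#' Using traces that reflect history up to but excluding the current step's
#' increments: every presynaptic (excitatory) spike depresses its row of the
#' plastic fractions by `eta * A_post`; every postsynaptic spike potentiates
#' its column by `eta * A_pre`. Fractions are clamped at zero from below.
#' Call this *before* [stdp_trace_step()] within a step; exactly coincident
#' pre/post spike pairs then produce no interaction through each other's
#' fresh increments.
#'
#' @param pstate an `ftsts_plastic_state`.
#' @param spikes_E,spikes_I logical spike masks.
#' @param params a [stdp_params()] object.
#' @return the updated plastic state.
#' @export
stdp_weight_update <- function(pstate, spikes_E, spikes_I, params) {
  pre <- which(spikes_E)
  for (i in pre) {
    pstate$Wp_EE[i, ] <- pstate$Wp_EE[i, ] - params$eta * pstate$A_E
    pstate$Wp_EI[i, ] <- pstate$Wp_EI[i, ] - params$eta * pstate$A_I
  }
  for (j in which(spikes_E)) {
    pstate$Wp_EE[, j] <- pstate$Wp_EE[, j] + params$eta * pstate$A_E
  }
  for (j in which(spikes_I)) {
    pstate$Wp_EI[, j] <- pstate$Wp_EI[, j] + params$eta * pstate$A_E
  }
  pstate$Wp_EE[pstate$Wp_EE < 0] <- 0
  pstate$Wp_EI[pstate$Wp_EI < 0] <- 0
  pstate
}

#' Average excitatory-to-inhibitory synaptic weight
#'
#' The network efficacy readout: the mean over postsynaptic inhibitory
#' neurons of their summed effective incoming excitatory weight
#' \eqn{\sum_i \bar W^{EI}_{i,j} W^{p,EI}_{i,j}} (nS). With all plastic
#' fractions at one this equals the row budget `W0_EI` by row-sum
#' conservation.
#'
#' @param W_EI base E-to-I matrix (nS), presynaptic rows.
#' @param Wp_EI plastic fraction matrix of the same shape.
#' @return average weight in nS.
#' @examples
#' W <- build_connectivity(connectivity_spec(N_E = 10, N_I = 10))
#' average_ei_weight(W$W_EI, matrix(1, 10, 10))  # = W0_EI
#' @export
average_ei_weight <- function(W_EI, Wp_EI) {
  if (!all(dim(W_EI) == dim(Wp_EI))) {
    stop("average_ei_weight: shape mismatch", call. = FALSE)
  }
  sum(W_EI * Wp_EI) / ncol(W_EI)
}
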