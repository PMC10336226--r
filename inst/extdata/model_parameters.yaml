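# Reference configuration: neuron, plasticity and connectivity constants of
# the neocortical seizure network, in the package's default calibration.
# Units: mV, nS, pF, pA, ms, mM.
C: 100            # membrane capacitance (pF)
g_L: 4            # leak conductance (nS)
E_L: -57          # leak reversal (mV)
E_E: 0            # glutamatergic reversal (mV)
E_K: -90          # potassium reversal (mV)
f0: 2             # baseline rate at threshold (Hz)
beta: 1.5         # threshold softness (mV)
tau_ref: 5        # refractory period (ms)
tau_syn: 15       # synaptic decay (ms)
tau_phi: 100      # threshold relaxation (ms)
phi0: -55         # baseline threshold (mV)
delta_phi: 3.5    # post-spike threshold increment (mV), calibrated
delta_K: 40       # sAHP increment numerator (nS); jump = delta_K / tau_K
f_max: 0.2        # conductance rate-scaling factor (per ms)
V_d: 0.2357       # chloride volume of distribution (pL)
Faraday: 96500    # C/mol
Cl_in_eq: 6       # equilibrium internal chloride (mM)
Cl_out: 110       # external chloride (mM)
tau_Cl: 5000      # chloride relaxation (ms)
tau_K: 5000       # sAHP decay (ms)
dt: 0.5           # Euler step (ms)
syn_gain: 5       # synaptic efficacy gain, calibrated
# plasticity
eta: 0.001        # STDP learning rate
tau_STDP: 15      # trace time constant (ms)
A0: 1             # trace increment per spike
# connectivity (see connectivity_spec())
N_E: 500
N_I: 500
sigma_E: 0.02
sigma_I: 0.03
W0_EE: 104
W0_EI: 100
W0_II: 250
W0_IE: 250
W_UI: 50
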