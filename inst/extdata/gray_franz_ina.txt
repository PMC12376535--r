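# Minimal fast sodium current, Gray-Franz style (parsimonious ventricular
# m^3 h formulation). I = g * m^3 * h * (v - E_rev).
#
# Activation: instantaneous-kinetics Boltzmann with a constant 0.12 ms time
# constant. Inactivation: Boltzmann with a skewed-bell time constant
# tau_h(v) = 2 * tau_h0 * exp(delta_h * x) / (1 + exp(x)),
# x = (v - h_V_half) / |h_k|, tau_h0 = 6.80678 ms, delta_h = 0.799163.
#
# Baseline conductance density 20 nS/pF gives a peak I-V current density of
# about -1000 pA/pF under an ideal clamp.

name: gray_franz_style_ina
type: hh_sodium
g_max_nS_per_pF: 20
E_rev_mV: 65
m_V_half_mV: -41
m_k_mV: 4
tau_m_base_ms: 0.12
tau_m_amp_ms: 0
h_V_half_mV: -74.9
h_k_mV: -4.4
tau_h_base_ms: 0
tau_h_amp_ms: 13.61356
tau_h_vmid_mV: -74.9
tau_h_k_mV: 4.4
tau_h_delta: 0.799163
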