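# O'Hara-style human-ventricular fast sodium current (fast component,
# non-phosphorylated pathway): I = g * m^3 * (0.99 hf + 0.01 hs) * j * (v - E).
# The rate equations of this formulation are built into the package
# (see ohara_ina()); this file carries its conductance and reversal.
#
# Baseline conductance density 75 nS/pF.

name: ohara_style_ina
type: ohara_ina
g_max_nS_per_pF: 75
E_rev_mV: 70
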