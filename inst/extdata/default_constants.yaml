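# Default dual-energy decomposition constants (synthetic, version 1).
# Plausible 90/Sn150-kVp values: pure matrix ~2000/1200 HU, pure adipose
# ~-110/-90 HU, fraction-free baseline 15 HU at both energies.
mu_lo: 2000.0
mu_hi: 1200.0
gamma_lo: 14.70588235294118
gamma_hi: 14.70588235294118
beta_lo: -119.5652173913043
beta_hi: -97.82608695652173
delta_lo: 0.0
delta_hi: 0.0
t: 0.92
g: 1.02
l: 3.06
lam: 2.11
det_tol: 1.0e-06
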