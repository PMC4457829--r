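# Microscopic rate constants for the wild-type-like protoglobin (MaPgb*,
# Cys101Ser) from the published global fit of CO rebinding at 20 C.
# Units: s^-1, except kin_r/kin_t in M^-1 s^-1.
# Naming note: kd2/k_d2 are the t-state primary<->secondary docking-site
# migration rates (the scheme's kd/k-d); kdiss_r/kdiss_t are the thermal
# Fe-CO dissociation rates (the scheme's kd,r/kd,t), here derived from
# the measured apparent dissociation rates via
# kdiss = koff * (kout + kg) / kout.
k1 = 1.3e5
k_1 = 5e5
k2 = 6e4        # tied to k3
k_2 = 2e4       # tied to k_3
k3 = 6e4
k_3 = 2e4
kc = 1e7
k_c = 1e7
kd2 = 1e7
k_d2 = 1e7
kg_r = 5e7
kg_t = 6e6
kdiss_r = 0.042666666666666665   # from koff = 0.032 s^-1
kdiss_t = 0.08424                # from koff = 0.081 s^-1
kin_r = 7.8e7
kin_t = 3e7
kout = 1.5e8
co_atm = 1.0
temperature_C = 20
co_solubility = 1e-3
photolysis_yield = 1.0
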