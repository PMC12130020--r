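N_exc: 500.0
N_inh: 125.0
g_ratio: 5.0
K: 125.0
J_exc: 1.0
delay: 1.5
ext_rate: 1820.0
ext_w: 1.0
duration: 4000.0
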