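omega_v,g_v,alpha2,gamma2
956,1,0.80,1.60
971,1,0.55,1.10
984,1,0.30,0.90
993,1,0.20,0.60
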