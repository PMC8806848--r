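omega_v,g_v,alpha2,gamma2
941,1,0.15,0.45
950,1,0.25,0.70
965,1,0.50,1.00
968,1,0.40,0.80
978,1,0.35,0.75
988,1,0.20,0.50
991,1,0.10,0.30
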