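# extdata

`synthetic_modes_mannose_alpha.csv` / `synthetic_modes_mannose_beta.csv`:
SYNTHETIC vibrational mode tables for the anomeric window of hydrated
alpha/beta D-mannopyranose. The frequencies are the computed harmonic
values for the hydrated structures; the polarizability-derivative
invariants (`alpha2`, `gamma2`) are invented stand-ins on a plausible
scale — no DFT output is shipped — so they exercise the cross-section
and broadening machinery, not reproduce computed intensities.
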