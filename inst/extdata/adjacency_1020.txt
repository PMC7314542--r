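F3 Fz
Fz F4
F3 C3
Fz Cz
F4 C4
C3 Cz
Cz C4
C3 P3
Cz Pz
C4 P4
P3 Pz
Pz P4
P3 O1
P4 O2
O1 O2
Pz O1
Pz O2
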