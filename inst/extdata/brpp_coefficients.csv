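descriptor,coefficient,se,t_value
ALFA polarizability (DIP),0.653,0.056,11.755
WPSA-3 weighted PPSA (Zefirov's PC),-10.969,0.860,-12.756
HASA-1/TMSA (Zefirov's PC),-73.908,14.802,-4.993
Tot point-charge compd. of the molecular dipole,-7.799,0.918,-8.495
PNSA-2 total charge weighted PNSA,-0.036,0.005,-7.757
Final heat of formation,-0.059,0.016,-3.596
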