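descriptor,ALFA polarizability (DIP),WPSA-3 weighted PPSA (Zefirov's PC),HASA-1/TMSA (Zefirov's PC),Tot point-charge compd. of the molecular dipole,PNSA-2 total charge weighted PNSA,Final heat of formation
ALFA polarizability (DIP),1.000,0.177,0.776,0.039,-0.190,-0.559
WPSA-3 weighted PPSA (Zefirov's PC),0.177,1.000,0.266,0.269,-0.104,-0.255
HASA-1/TMSA (Zefirov's PC),0.776,0.266,1.000,0.129,-0.541,-0.592
Tot point-charge compd. of the molecular dipole,0.039,0.269,0.129,1.000,-0.192,-0.497
PNSA-2 total charge weighted PNSA,-0.190,-0.104,-0.541,-0.192,1.000,0.325
Final heat of formation,-0.559,-0.255,-0.592,-0.497,0.325,1.000
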