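==== Secondary Structure Definition, synthetic fixture ====
  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA
    1    1 A A  H
    2    2 A L  H
    3    3 A K  H
    4    4 A G  T
    5    5 A S
    6        !
    7    7 B V  E
    8    8 B I  E
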