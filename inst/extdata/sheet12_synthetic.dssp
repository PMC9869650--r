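==== Secondary Structure Definition, synthetic fixture ====
  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA
    1    1 A A   
    2    2 A A  E
    3    3 A A  E
    4    4 A A  E
    5    5 A A  E
    6    6 A A   
    7  101 A A   
    8  102 A A  E
    9  103 A A  E
   10  104 A A  E
   11  105 A A  E
   12  106 A A   
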