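==== Secondary Structure Definition, synthetic fixture ====
  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA
    1    1 A A   
    2    2 A A  H
    3    3 A A  H
    4    4 A A  H
    5    5 A A  H
    6    6 A A  H
    7    7 A A  H
    8    8 A A  H
    9    9 A A  H
   10   10 A A  H
   11   11 A A  H
   12   12 A A  H
   13   13 A A  H
   14   14 A A  H
   15   15 A A  H
   16   16 A A  H
   17   17 A A  T
   18   18 A A   
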