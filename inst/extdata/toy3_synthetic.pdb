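HEADER    SYNTHETIC BACKBONE                      01-JAN-26   TOY3
REMARK   2 RESOLUTION. 2.50 ANGSTROMS.
ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C
ATOM      3  C   ALA A   1       2.009  -1.422   0.000  1.00  0.00           C
ATOM      4  O   ALA A   1       2.910  -1.749  -0.773  1.00  0.00           O
ATOM      5  N   GLY A   2       1.463  -2.263   0.872  1.00  0.00           N
ATOM      6  CA  GLY A   2       1.899  -3.650   0.974  1.00  0.00           C
ATOM      7  C   GLY A   2       1.768  -4.370  -0.364  1.00  0.00           C
ATOM      8  O   GLY A   2       2.689  -5.059  -0.802  1.00  0.00           O
ATOM      9  N   MET A   3       0.618  -4.205  -1.008  1.00  0.00           N
ATOM     10  CA  MET A   3       0.364  -4.838  -2.297  1.00  0.00           C
ATOM     11  C   MET A   3       1.421  -4.443  -3.323  1.00  0.00           C
ATOM     12  O   MET A   3       1.961  -5.294  -4.030  1.00  0.00           O
TER
END
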