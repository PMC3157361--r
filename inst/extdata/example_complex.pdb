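ATOM      1  CA  VAL R   1       0.000   0.000   0.000  1.00  0.00           C
ATOM      2  CA  VAL R   2      10.000   0.000   0.000  1.00  0.00           C
ATOM      3  CA  GLU R   3      20.000   0.000   0.000  1.00  0.00           C
ATOM      4  CA  TRP R   4      30.000   0.000   0.000  1.00  0.00           C
ATOM      5  CA  PHE R   5      40.000   0.000   0.000  1.00  0.00           C
ATOM      6  CA  LYS R   6      50.000   0.000   0.000  1.00  0.00           C
ATOM      7  CA  SER L   1       0.869  -0.050   4.582  1.00  0.00           C
ATOM      8  CA  ASP L   2       9.511   0.121   5.014  1.00  0.00           C
ATOM      9  CA  PRO L   3      19.925   0.808   4.890  1.00  0.00           C
ATOM     10  CA  SER L   4      30.880  -0.723   5.406  1.00  0.00           C
ATOM     11  CA  LEU L   5      40.956   0.978   4.947  1.00  0.00           C
ATOM     12  CA  SER L   6      49.235   0.893 120.000  1.00  0.00           C
END
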