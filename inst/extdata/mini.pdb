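REMARK synthetic mini fixture: one alanine, two waters
ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00 10.00           N
ATOM      2  CA  ALA A   1       2.000   2.500   3.500  1.00 11.00
ATOM      3  C   ALA A   1       3.400   2.100   3.200  1.00 12.00           C
ATOM      4  O   ALA A   1       4.100   3.000   2.800  1.00 13.00           O
ATOM      5  CB AALA A   1       2.100   4.000   3.900  0.60 14.00           C
ATOM      6  CB BALA A   1       2.200   4.100   3.800  0.40 14.50           C
HETATM    7  O   HOH A 101      10.000  10.000  10.000  1.00 20.00           O
HETATM    8  H1  HOH A 101      10.957  10.000  10.000  1.00 20.00           H
HETATM    9  H2  HOH A 101       9.760  10.927  10.000  1.00 20.00           H
HETATM   10  O   HOH A 102      12.500  11.000   9.000  1.00 21.00           O
HETATM   11  H1  HOH A 102      13.457  11.000   9.000  1.00 21.00           H
HETATM   12  H2  HOH A 102      12.260  11.927   9.000  1.00 21.00           H
END
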