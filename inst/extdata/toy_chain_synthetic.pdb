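HEADER    SYNTHETIC TOY CHAIN FOR CONTACT-GRAPH TESTS
REMARK    SYNTHETIC COORDINATES, NOT A REAL PROTEIN
ATOM      1  N   ALA A   1       2.600   0.300   0.000  1.00  0.00           N
ATOM      2  CA  ALA A   1       3.800   0.000   0.000  1.00  0.00           C
ATOM      3  C   ALA A   1       5.000   0.600   0.000  1.00  0.00           C
ATOM      4  O   ALA A   1       5.100   1.800   0.000  1.00  0.00           O
ATOM      5  CB  ALA A   1       3.800  -1.000   1.200  1.00  0.00           C
ATOM      6  N   VAL A   2       6.400   0.300   0.000  1.00  0.00           N
ATOM      7  CA  VAL A   2       7.600   0.000   0.000  1.00  0.00           C
ATOM      8  C   VAL A   2       8.800   0.600   0.000  1.00  0.00           C
ATOM      9  O   VAL A   2       8.900   1.800   0.000  1.00  0.00           O
ATOM     10  CB  VAL A   2       7.600  -1.000   1.200  1.00  0.00           C
ATOM     11  N   LEU A   3      10.200   0.300   0.000  1.00  0.00           N
ATOM     12  CA  LEU A   3      11.400   0.000   0.000  1.00  0.00           C
ATOM     13  C   LEU A   3      12.600   0.600   0.000  1.00  0.00           C
ATOM     14  O   LEU A   3      12.700   1.800   0.000  1.00  0.00           O
ATOM     15  CB  LEU A   3      11.400  -1.000   1.200  1.00  0.00           C
ATOM     16  N   ILE A   4      14.000   0.300   0.000  1.00  0.00           N
ATOM     17  CA  ILE A   4      15.200   0.000   0.000  1.00  0.00           C
ATOM     18  C   ILE A   4      16.400   0.600   0.000  1.00  0.00           C
ATOM     19  O   ILE A   4      16.500   1.800   0.000  1.00  0.00           O
ATOM     20  CB  ILE A   4      15.200  -1.000   1.200  1.00  0.00           C
ATOM     21  N   SER A   5      17.800   0.300   0.000  1.00  0.00           N
ATOM     22  CA  SER A   5      19.000   0.000   0.000  1.00  0.00           C
ATOM     23  C   SER A   5      20.200   0.600   0.000  1.00  0.00           C
ATOM     24  O   SER A   5      20.300   1.800   0.000  1.00  0.00           O
ATOM     25  CB  SER A   5      19.000  -1.000   1.200  1.00  0.00           C
ATOM     26  N   THR A   6      21.600   0.300   0.000  1.00  0.00           N
ATOM     27  CA  THR A   6      22.800   0.000   0.000  1.00  0.00           C
ATOM     28  C   THR A   6      24.000   0.600   0.000  1.00  0.00           C
ATOM     29  O   THR A   6      24.100   1.800   0.000  1.00  0.00           O
ATOM     30  CB  THR A   6      22.800  -1.000   1.200  1.00  0.00           C
ATOM     31  N   PHE A   7      25.400   0.300   0.000  1.00  0.00           N
ATOM     32  CA  PHE A   7      26.600   0.000   0.000  1.00  0.00           C
ATOM     33  C   PHE A   7      27.800   0.600   0.000  1.00  0.00           C
ATOM     34  O   PHE A   7      27.900   1.800   0.000  1.00  0.00           O
ATOM     35  CB  PHE A   7      26.600  -1.000   1.200  1.00  0.00           C
ATOM     36  N   TYR A   8      29.200   0.300   0.000  1.00  0.00           N
ATOM     37  CA  TYR A   8      30.400   0.000   0.000  1.00  0.00           C
ATOM     38  C   TYR A   8      31.600   0.600   0.000  1.00  0.00           C
ATOM     39  O   TYR A   8      31.700   1.800   0.000  1.00  0.00           O
ATOM     40  CB  TYR A   8      30.400  -1.000   1.200  1.00  0.00           C
ATOM     41  N   LYS A   9      33.000   0.300   0.000  1.00  0.00           N
ATOM     42  CA  LYS A   9      34.200   0.000   0.000  1.00  0.00           C
ATOM     43  C   LYS A   9      35.400   0.600   0.000  1.00  0.00           C
ATOM     44  O   LYS A   9      35.500   1.800   0.000  1.00  0.00           O
ATOM     45  CB  LYS A   9      34.200  -1.000   1.200  1.00  0.00           C
ATOM     46  N   ASP A  10      36.800   0.300   0.000  1.00  0.00           N
ATOM     47  CA  ASP A  10      38.000   0.000   0.000  1.00  0.00           C
ATOM     48  C   ASP A  10      39.200   0.600   0.000  1.00  0.00           C
ATOM     49  O   ASP A  10      39.300   1.800   0.000  1.00  0.00           O
ATOM     50  CB  ASP A  10      38.000  -1.000   1.200  1.00  0.00           C
ATOM     51  N   MET A  11      40.600   0.300   0.000  1.00  0.00           N
ATOM     52  CA  MET A  11      41.800   0.000   0.000  1.00  0.00           C
ATOM     53  C   MET A  11      43.000   0.600   0.000  1.00  0.00           C
ATOM     54  O   MET A  11      43.100   1.800   0.000  1.00  0.00           O
ATOM     55  CB  MET A  11      41.800  -1.000   1.200  1.00  0.00           C
ATOM     56  N   GLY A  12      44.400   0.300   0.000  1.00  0.00           N
ATOM     57  CA  GLY A  12      45.600   0.000   0.000  1.00  0.00           C
ATOM     58  C   GLY A  12      46.800   0.600   0.000  1.00  0.00           C
ATOM     59  O   GLY A  12      46.900   1.800   0.000  1.00  0.00           O
TER
END
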