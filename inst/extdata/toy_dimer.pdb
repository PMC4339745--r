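ATOM      1  N   SER A   1      -0.500   0.800   1.100  1.00  0.00           N
ATOM      2  CA  SER A   1       0.000   0.000   1.100  1.00  0.00           C
ATOM      3  C   SER A   1       0.800  -0.900   1.500  1.00  0.00           C
ATOM      4  O   SER A   1       0.700  -1.900   0.800  1.00  0.00           O
ATOM      5  CB  SER A   1       0.300   1.200   2.200  1.00  0.00           C
ATOM      6  N   LYS A   2       3.300   0.800   0.000  1.00  0.00           N
ATOM      7  CA  LYS A   2       3.800   0.000   0.000  1.00  0.00           C
ATOM      8  C   LYS A   2       4.600  -0.900   0.400  1.00  0.00           C
ATOM      9  O   LYS A   2       4.500  -1.900  -0.300  1.00  0.00           O
ATOM     10  CB  LYS A   2       4.100   1.200   1.100  1.00  0.00           C
ATOM     11  N   ALA A   3       7.100   0.800   1.100  1.00  0.00           N
ATOM     12  CA  ALA A   3       7.600   0.000   1.100  1.00  0.00           C
ATOM     13  C   ALA A   3       8.400  -0.900   1.500  1.00  0.00           C
ATOM     14  O   ALA A   3       8.300  -1.900   0.800  1.00  0.00           O
ATOM     15  CB  ALA A   3       7.900   1.200   2.200  1.00  0.00           C
ATOM     16  N   GLY A   4      10.900   0.800   0.000  1.00  0.00           N
ATOM     17  CA  GLY A   4      11.400   0.000   0.000  1.00  0.00           C
ATOM     18  C   GLY A   4      12.200  -0.900   0.400  1.00  0.00           C
ATOM     19  O   GLY A   4      12.100  -1.900  -0.300  1.00  0.00           O
ATOM     20  N   LEU A   5      14.700   0.800   1.100  1.00  0.00           N
ATOM     21  CA  LEU A   5      15.200   0.000   1.100  1.00  0.00           C
ATOM     22  C   LEU A   5      16.000  -0.900   1.500  1.00  0.00           C
ATOM     23  O   LEU A   5      15.900  -1.900   0.800  1.00  0.00           O
ATOM     24  CB  LEU A   5      15.500   1.200   2.200  1.00  0.00           C
ATOM     25  N   GLU A   6      18.500   0.800   0.000  1.00  0.00           N
ATOM     26  CA  GLU A   6      19.000   0.000   0.000  1.00  0.00           C
ATOM     27  C   GLU A   6      19.800  -0.900   0.400  1.00  0.00           C
ATOM     28  O   GLU A   6      19.700  -1.900  -0.300  1.00  0.00           O
ATOM     29  CB  GLU A   6      19.300   1.200   1.100  1.00  0.00           C
ATOM     30  N   ARG B   1       0.100   5.800   2.100  1.00  0.00           N
ATOM     31  CA  ARG B   1       0.600   5.200   2.400  1.00  0.00           C
ATOM     32  C   ARG B   1       1.400   4.600   3.000  1.00  0.00           C
ATOM     33  O   ARG B   1       1.300   3.900   4.000  1.00  0.00           O
ATOM     34  CB  ARG B   1       0.900   4.000   1.400  1.00  0.00           C
ATOM     35  N   THR B   2       3.900   5.800   1.000  1.00  0.00           N
ATOM     36  CA  THR B   2       4.400   5.200   1.300  1.00  0.00           C
ATOM     37  C   THR B   2       5.200   4.600   1.900  1.00  0.00           C
ATOM     38  O   THR B   2       5.100   3.900   2.900  1.00  0.00           O
ATOM     39  CB  THR B   2       4.700   4.000   0.300  1.00  0.00           C
ATOM     40  N   PHE B   3       7.700   5.800   2.100  1.00  0.00           N
ATOM     41  CA  PHE B   3       8.200   5.200   2.400  1.00  0.00           C
ATOM     42  C   PHE B   3       9.000   4.600   3.000  1.00  0.00           C
ATOM     43  O   PHE B   3       8.900   3.900   4.000  1.00  0.00           O
ATOM     44  CB  PHE B   3       8.500   4.000   1.400  1.00  0.00           C
ATOM     45  N   ASP B   4      11.500   5.800   1.000  1.00  0.00           N
ATOM     46  CA  ASP B   4      12.000   5.200   1.300  1.00  0.00           C
ATOM     47  C   ASP B   4      12.800   4.600   1.900  1.00  0.00           C
ATOM     48  O   ASP B   4      12.700   3.900   2.900  1.00  0.00           O
ATOM     49  CB  ASP B   4      12.300   4.000   0.300  1.00  0.00           C
ATOM     50  N   VAL B   5      15.300   5.800   2.100  1.00  0.00           N
ATOM     51  CA  VAL B   5      15.800   5.200   2.400  1.00  0.00           C
ATOM     52  C   VAL B   5      16.600   4.600   3.000  1.00  0.00           C
ATOM     53  O   VAL B   5      16.500   3.900   4.000  1.00  0.00           O
ATOM     54  CB  VAL B   5      16.100   4.000   1.400  1.00  0.00           C
ATOM     55  N   TYR B   6      19.100   5.800   1.000  1.00  0.00           N
ATOM     56  CA  TYR B   6      19.600   5.200   1.300  1.00  0.00           C
ATOM     57  C   TYR B   6      20.400   4.600   1.900  1.00  0.00           C
ATOM     58  O   TYR B   6      20.300   3.900   2.900  1.00  0.00           O
ATOM     59  CB  TYR B   6      19.900   4.000   0.300  1.00  0.00           C
TER
END
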