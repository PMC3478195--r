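# Synthetic Atomic Contact Energy table (stand-in parameterisation).
# The published 18x18 contact-energy values are not redistributed here;
# these energies are a deterministic synthetic set with the documented
# file format. Rebuild a table from your own counts with buildAceTable(),
# or edit this file. Sections: [types], [energies] (0-based upper
# triangle), [typing] (residue atom type).
[types]
N_BB
CA_GLY
CA
C_BB
O_BB
C_ALIPH
C_AROM
O_HYDROXYL
O_CARBOXYL
N_AMIDE
O_AMIDE
N_POS
N_AROM
S
C_POLAR
C_BRANCH
C_PRO
C_MISC
[energies]
0 0 -0.430
0 1 0.185
0 2 0.782
0 3 1.049
0 4 0.845
0 5 0.278
0 6 -0.356
0 7 -0.726
0 8 -0.637
0 9 -0.137
0 10 0.514
0 11 0.974
0 12 1.003
0 13 0.586
0 14 -0.059
0 15 -0.595
0 16 -0.741
0 17 -0.421
1 1 1.035
1 2 0.502
1 3 -0.581
1 4 -0.523
1 5 0.586
1 6 1.014
1 7 0.092
1 8 -0.739
1 9 -0.181
1 10 0.894
1 11 0.807
1 12 -0.306
1 13 -0.707
1 14 0.231
1 15 1.042
1 16 0.460
1 17 -0.606
2 2 -0.750
2 3 0.480
2 4 0.799
2 5 -0.673
2 6 0.126
2 7 0.992
2 8 -0.464
2 9 -0.225
2 10 1.049
2 11 -0.157
2 12 -0.516
2 13 0.963
2 14 0.200
2 15 -0.700
2 16 0.746
2 17 0.548
3 3 0.325
3 4 -0.475
3 5 1.026
3 6 -0.699
3 7 0.702
3 8 0.071
3 9 -0.268
3 10 0.933
3 11 -0.749
3 12 0.879
3 13 -0.177
3 14 -0.029
3 15 0.777
3 16 -0.727
3 17 0.997
4 4 0.749
4 5 -0.423
4 6 0.696
4 7 -0.368
4 8 0.640
4 9 -0.310
4 10 0.580
4 11 -0.249
4 12 0.518
4 13 -0.186
4 14 0.454
4 15 -0.121
4 16 0.388
4 17 -0.055
5 5 0.188
5 6 0.663
5 7 -0.705
5 8 1.001
5 9 -0.351
5 10 0.097
5 11 0.735
5 12 -0.729
5 13 0.967
5 14 -0.273
5 15 0.008
5 16 0.800
5 17 -0.744
6 6 -0.711
6 7 0.166
6 8 1.001
6 9 -0.390
6 10 -0.369
6 11 1.009
6 12 0.141
6 13 -0.704
6 14 0.683
6 15 0.676
6 16 -0.707
6 17 0.151
7 7 1.015
7 8 0.641
7 9 -0.427
7 10 -0.679
7 11 0.241
7 12 1.033
7 13 0.577
7 14 -0.482
7 15 -0.648
7 16 0.314
7 17 1.044
8 8 0.072
8 9 -0.463
8 10 -0.739
8 11 -0.638
8 12 -0.203
8 13 0.382
8 14 0.868
8 15 1.050
8 16 0.850
8 17 0.354
9 9 -0.497
9 10 -0.530
9 11 -0.560
9 12 -0.588
9 13 -0.615
9 14 -0.639
9 15 -0.661
9 16 -0.680
9 17 -0.698
10 10 -0.115
10 11 0.379
10 12 0.805
10 13 1.032
10 14 0.993
10 15 0.699
10 16 0.240
10 17 -0.247
11 11 1.040
11 12 0.621
11 13 -0.370
11 14 -0.730
11 15 -0.021
11 16 0.895
11 17 0.907
12 12 -0.697
12 13 0.026
12 14 1.048
12 15 -0.093
12 16 -0.648
12 17 0.720
13 13 0.851
13 14 -0.747
13 15 0.756
13 16 0.164
13 17 -0.477
14 14 1.028
14 15 -0.690
14 16 0.935
14 17 -0.563
15 15 1.046
15 16 -0.611
15 17 0.614
16 16 0.088
16 17 0.969
17 17 -0.127
[typing]
GLY N 0
GLY CA 1
GLY C 3
GLY O 4
GLY OXT 4
ALA N 0
ALA CA 2
ALA C 3
ALA O 4
ALA OXT 4
ALA CB 5
VAL N 0
VAL CA 2
VAL C 3
VAL O 4
VAL OXT 4
VAL CB 15
VAL CG1 15
VAL CG2 15
LEU N 0
LEU CA 2
LEU C 3
LEU O 4
LEU OXT 4
LEU CB 5
LEU CG 15
LEU CD1 15
LEU CD2 15
ILE N 0
ILE CA 2
ILE C 3
ILE O 4
ILE OXT 4
ILE CB 15
ILE CG1 15
ILE CG2 15
ILE CD1 15
PRO N 0
PRO CA 2
PRO C 3
PRO O 4
PRO OXT 4
PRO CB 16
PRO CG 16
PRO CD 16
PHE N 0
PHE CA 2
PHE C 3
PHE O 4
PHE OXT 4
PHE CB 5
PHE CG 6
PHE CD1 6
PHE CD2 6
PHE CE1 6
PHE CE2 6
PHE CZ 6
TRP N 0
TRP CA 2
TRP C 3
TRP O 4
TRP OXT 4
TRP CB 5
TRP CG 6
TRP CD1 6
TRP CD2 6
TRP CE2 6
TRP CE3 6
TRP CZ2 6
TRP CZ3 6
TRP CH2 6
TRP NE1 12
MET N 0
MET CA 2
MET C 3
MET O 4
MET OXT 4
MET CB 5
MET CG 5
MET SD 13
MET CE 5
CYS N 0
CYS CA 2
CYS C 3
CYS O 4
CYS OXT 4
CYS CB 5
CYS SG 13
SER N 0
SER CA 2
SER C 3
SER O 4
SER OXT 4
SER CB 5
SER OG 7
THR N 0
THR CA 2
THR C 3
THR O 4
THR OXT 4
THR CB 15
THR OG1 7
THR CG2 15
TYR N 0
TYR CA 2
TYR C 3
TYR O 4
TYR OXT 4
TYR CB 5
TYR CG 6
TYR CD1 6
TYR CD2 6
TYR CE1 6
TYR CE2 6
TYR CZ 6
TYR OH 7
ASN N 0
ASN CA 2
ASN C 3
ASN O 4
ASN OXT 4
ASN CB 5
ASN CG 14
ASN OD1 10
ASN ND2 9
GLN N 0
GLN CA 2
GLN C 3
GLN O 4
GLN OXT 4
GLN CB 5
GLN CG 5
GLN CD 14
GLN OE1 10
GLN NE2 9
ASP N 0
ASP CA 2
ASP C 3
ASP O 4
ASP OXT 4
ASP CB 5
ASP CG 14
ASP OD1 8
ASP OD2 8
GLU N 0
GLU CA 2
GLU C 3
GLU O 4
GLU OXT 4
GLU CB 5
GLU CG 5
GLU CD 14
GLU OE1 8
GLU OE2 8
LYS N 0
LYS CA 2
LYS C 3
LYS O 4
LYS OXT 4
LYS CB 5
LYS CG 5
LYS CD 5
LYS CE 17
LYS NZ 11
ARG N 0
ARG CA 2
ARG C 3
ARG O 4
ARG OXT 4
ARG CB 5
ARG CG 5
ARG CD 17
ARG NE 11
ARG CZ 14
ARG NH1 11
ARG NH2 11
HIS N 0
HIS CA 2
HIS C 3
HIS O 4
HIS OXT 4
HIS CB 5
HIS CG 6
HIS CD2 6
HIS CE1 6
HIS ND1 12
HIS NE2 12
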