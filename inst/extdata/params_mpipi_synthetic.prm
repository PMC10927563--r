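# Synthetic residue-level parameter set (Mpipi functional form).
# Pair epsilons are built by geometric-mean combination of per-residue
# stickiness values with cation-pi boosts (R-aromatic x2.0, K-aromatic
# x1.3); they are NOT the published Mpipi pair table. Sigma: arithmetic
# mean of bead diameters. All pairs use mu = 2, nu = 1; cutoff = 3 sigma.
# units: length A, energy kcal/mol, mass Da, charge e
[meta]
version = mpipi

[beads]
# residue mass charge sigma
A 71.079 0.0 5.04
C 103.143 0.0 5.48
D 115.089 -1.0 5.58
E 129.116 -1.0 5.92
F 147.177 0.0 6.36
G 57.052 0.0 4.50
H 137.141 0.0 6.08
I 113.160 0.0 6.18
K 128.175 1.0 6.36
L 113.160 0.0 6.18
M 131.197 0.0 6.18
N 114.104 0.0 5.68
P 97.117 0.0 5.56
Q 128.131 0.0 6.02
R 156.188 1.0 6.56
S 87.078 0.0 5.18
T 101.105 0.0 5.62
V 99.133 0.0 5.86
W 186.214 0.0 6.78
Y 163.176 0.0 6.46

[pairs]
# res_i res_j epsilon sigma mu nu_wf
A A 0.1300 5.040 2 1
A C 0.1612 5.260 2 1
A D 0.1249 5.310 2 1
A E 0.1249 5.480 2 1
A F 0.2040 5.700 2 1
A G 0.1140 4.770 2 1
A H 0.1803 5.560 2 1
A I 0.1652 5.610 2 1
A K 0.1140 5.700 2 1
A L 0.1652 5.610 2 1
A M 0.1612 5.610 2 1
A N 0.1349 5.360 2 1
A P 0.1249 5.300 2 1
A Q 0.1349 5.530 2 1
A R 0.1530 5.800 2 1
A S 0.1196 5.110 2 1
A T 0.1249 5.330 2 1
A V 0.1530 5.450 2 1
A W 0.2280 5.910 2 1
A Y 0.2133 5.750 2 1
C C 0.2000 5.480 2 1
C D 0.1549 5.530 2 1
C E 0.1549 5.700 2 1
C F 0.2530 5.920 2 1
C G 0.1414 4.990 2 1
C H 0.2236 5.780 2 1
C I 0.2049 5.830 2 1
C K 0.1414 5.920 2 1
C L 0.2049 5.830 2 1
C M 0.2000 5.830 2 1
C N 0.1673 5.580 2 1
C P 0.1549 5.520 2 1
C Q 0.1673 5.750 2 1
C R 0.1897 6.020 2 1
C S 0.1483 5.330 2 1
C T 0.1549 5.550 2 1
C V 0.1897 5.670 2 1
C W 0.2828 6.130 2 1
C Y 0.2646 5.970 2 1
D D 0.1200 5.580 2 1
D E 0.1200 5.750 2 1
D F 0.1960 5.970 2 1
D G 0.1095 5.040 2 1
D H 0.1732 5.830 2 1
D I 0.1587 5.880 2 1
D K 0.1095 5.970 2 1
D L 0.1587 5.880 2 1
D M 0.1549 5.880 2 1
D N 0.1296 5.630 2 1
D P 0.1200 5.570 2 1
D Q 0.1296 5.800 2 1
D R 0.1470 6.070 2 1
D S 0.1149 5.380 2 1
D T 0.1200 5.600 2 1
D V 0.1470 5.720 2 1
D W 0.2191 6.180 2 1
D Y 0.2049 6.020 2 1
E E 0.1200 5.920 2 1
E F 0.1960 6.140 2 1
E G 0.1095 5.210 2 1
E H 0.1732 6.000 2 1
E I 0.1587 6.050 2 1
E K 0.1095 6.140 2 1
E L 0.1587 6.050 2 1
E M 0.1549 6.050 2 1
E N 0.1296 5.800 2 1
E P 0.1200 5.740 2 1
E Q 0.1296 5.970 2 1
E R 0.1470 6.240 2 1
E S 0.1149 5.550 2 1
E T 0.1200 5.770 2 1
E V 0.1470 5.890 2 1
E W 0.2191 6.350 2 1
E Y 0.2049 6.190 2 1
F F 0.3200 6.360 2 1
F G 0.1789 5.430 2 1
F H 0.2828 6.220 2 1
F I 0.2592 6.270 2 1
F K 0.2326 6.360 2 1
F L 0.2592 6.270 2 1
F M 0.2530 6.270 2 1
F N 0.2117 6.020 2 1
F P 0.1960 5.960 2 1
F Q 0.2117 6.190 2 1
F R 0.4800 6.460 2 1
F S 0.1876 5.770 2 1
F T 0.1960 5.990 2 1
F V 0.2400 6.110 2 1
F W 0.3578 6.570 2 1
F Y 0.3347 6.410 2 1
G G 0.1000 4.500 2 1
G H 0.1581 5.290 2 1
G I 0.1449 5.340 2 1
G K 0.1000 5.430 2 1
G L 0.1449 5.340 2 1
G M 0.1414 5.340 2 1
G N 0.1183 5.090 2 1
G P 0.1095 5.030 2 1
G Q 0.1183 5.260 2 1
G R 0.1342 5.530 2 1
G S 0.1049 4.840 2 1
G T 0.1095 5.060 2 1
G V 0.1342 5.180 2 1
G W 0.2000 5.640 2 1
G Y 0.1871 5.480 2 1
H H 0.2500 6.080 2 1
H I 0.2291 6.130 2 1
H K 0.1581 6.220 2 1
H L 0.2291 6.130 2 1
H M 0.2236 6.130 2 1
H N 0.1871 5.880 2 1
H P 0.1732 5.820 2 1
H Q 0.1871 6.050 2 1
H R 0.2121 6.320 2 1
H S 0.1658 5.630 2 1
H T 0.1732 5.850 2 1
H V 0.2121 5.970 2 1
H W 0.3162 6.430 2 1
H Y 0.2958 6.270 2 1
I I 0.2100 6.180 2 1
I K 0.1449 6.270 2 1
I L 0.2100 6.180 2 1
I M 0.2049 6.180 2 1
I N 0.1715 5.930 2 1
I P 0.1587 5.870 2 1
I Q 0.1715 6.100 2 1
I R 0.1944 6.370 2 1
I S 0.1520 5.680 2 1
I T 0.1587 5.900 2 1
I V 0.1944 6.020 2 1
I W 0.2898 6.480 2 1
I Y 0.2711 6.320 2 1
K K 0.1000 6.360 2 1
K L 0.1449 6.270 2 1
K M 0.1414 6.270 2 1
K N 0.1183 6.020 2 1
K P 0.1095 5.960 2 1
K Q 0.1183 6.190 2 1
K R 0.1342 6.460 2 1
K S 0.1049 5.770 2 1
K T 0.1095 5.990 2 1
K V 0.1342 6.110 2 1
K W 0.2600 6.570 2 1
K Y 0.2432 6.410 2 1
L L 0.2100 6.180 2 1
L M 0.2049 6.180 2 1
L N 0.1715 5.930 2 1
L P 0.1587 5.870 2 1
L Q 0.1715 6.100 2 1
L R 0.1944 6.370 2 1
L S 0.1520 5.680 2 1
L T 0.1587 5.900 2 1
L V 0.1944 6.020 2 1
L W 0.2898 6.480 2 1
L Y 0.2711 6.320 2 1
M M 0.2000 6.180 2 1
M N 0.1673 5.930 2 1
M P 0.1549 5.870 2 1
M Q 0.1673 6.100 2 1
M R 0.1897 6.370 2 1
M S 0.1483 5.680 2 1
M T 0.1549 5.900 2 1
M V 0.1897 6.020 2 1
M W 0.2828 6.480 2 1
M Y 0.2646 6.320 2 1
N N 0.1400 5.680 2 1
N P 0.1296 5.620 2 1
N Q 0.1400 5.850 2 1
N R 0.1587 6.120 2 1
N S 0.1241 5.430 2 1
N T 0.1296 5.650 2 1
N V 0.1587 5.770 2 1
N W 0.2366 6.230 2 1
N Y 0.2214 6.070 2 1
P P 0.1200 5.560 2 1
P Q 0.1296 5.790 2 1
P R 0.1470 6.060 2 1
P S 0.1149 5.370 2 1
P T 0.1200 5.590 2 1
P V 0.1470 5.710 2 1
P W 0.2191 6.170 2 1
P Y 0.2049 6.010 2 1
Q Q 0.1400 6.020 2 1
Q R 0.1587 6.290 2 1
Q S 0.1241 5.600 2 1
Q T 0.1296 5.820 2 1
Q V 0.1587 5.940 2 1
Q W 0.2366 6.400 2 1
Q Y 0.2214 6.240 2 1
R R 0.1800 6.560 2 1
R S 0.1407 5.870 2 1
R T 0.1470 6.090 2 1
R V 0.1800 6.210 2 1
R W 0.5367 6.670 2 1
R Y 0.5020 6.510 2 1
S S 0.1100 5.180 2 1
S T 0.1149 5.400 2 1
S V 0.1407 5.520 2 1
S W 0.2098 5.980 2 1
S Y 0.1962 5.820 2 1
T T 0.1200 5.620 2 1
T V 0.1470 5.740 2 1
T W 0.2191 6.200 2 1
T Y 0.2049 6.040 2 1
V V 0.1800 5.860 2 1
V W 0.2683 6.320 2 1
V Y 0.2510 6.160 2 1
W W 0.4000 6.780 2 1
W Y 0.3742 6.620 2 1
Y Y 0.3500 6.460 2 1

[bonds]
k = 9.6
r0 = 3.81

[electrostatics]
dielectric = 80.0
ionic_strength = 0.150
temperature = 300.0
coulomb_cutoff = 35.0
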