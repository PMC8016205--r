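# Double-zeta basis: standard cc-pVDZ primitive exponents (H, C, N, O) with
# general s-contractions for C/N/O taken from closed-shell ten-electron-ion RHF
# atomic orbitals computed in the uncontracted primitive set; Cartesian d.
ELEMENT H
SHELL S 4
  13.0100000   0.0196850
  1.9620000    0.1379770
  0.4446000    0.4781480
  0.1220000    0.5012400
SHELL S 1
  0.1220000    1.0000000
SHELL P 1
  0.7270000    1.0000000
ELEMENT C
SHELL S 9
  6665.0000000    0.0006922
  1000.0000000    0.0053299
  228.0000000    0.0270802
  64.7100000    0.1017557
  21.0600000    0.2748282
  7.4950000    0.4483979
  2.7970000    0.2850020
  0.5215000    0.0151415
  0.1596000   -0.0024212
SHELL S 9
  6665.0000000   -0.0001184
  1000.0000000   -0.0009849
  228.0000000   -0.0045113
  64.7100000   -0.0204452
  21.0600000   -0.0477400
  7.4950000   -0.1395636
  2.7970000   -0.0664567
  0.5215000    0.2250889
  0.1596000    0.8442137
SHELL S 1
  0.1596000    1.0000000
SHELL P 4
  9.4390000    0.0381090
  2.0020000    0.2094800
  0.5456000    0.5085570
  0.1517000    0.4688420
SHELL P 1
  0.1517000    1.0000000
SHELL D 1
  0.5500000    1.0000000
ELEMENT N
SHELL S 9
  9046.0000000    0.0006997
  1357.0000000    0.0053896
  309.3000000    0.0274071
  87.7300000    0.1032278
  28.5600000    0.2787612
  10.2100000    0.4484087
  3.8380000    0.2781739
  0.7466000    0.0154929
  0.2248000   -0.0022727
SHELL S 9
  9046.0000000   -0.0001334
  1357.0000000   -0.0010881
  309.3000000   -0.0051519
  87.7300000   -0.0224622
  28.5600000   -0.0562190
  10.2100000   -0.1498445
  3.8380000   -0.0817836
  0.7466000    0.3332375
  0.2248000    0.7597737
SHELL S 1
  0.2248000    1.0000000
SHELL P 4
  13.5500000   0.0399190
  2.9170000    0.2171690
  0.7973000    0.5103190
  0.2185000    0.4622140
SHELL P 1
  0.2185000    1.0000000
SHELL D 1
  0.8170000    1.0000000
ELEMENT O
SHELL S 9
  11720.0000000    0.0007228
  1759.0000000    0.0053103
  400.8000000    0.0293198
  105.3000000    0.1182016
  33.9800000    0.3004010
  12.3000000    0.4464419
  4.7560000    0.2426371
  1.0040000    0.0135256
  0.3008000   -0.0017055
SHELL S 9
  11720.0000000   -0.0001506
  1759.0000000   -0.0011523
  400.8000000   -0.0060956
  105.3000000   -0.0274541
  33.9800000   -0.0689948
  12.3000000   -0.1650067
  4.7560000   -0.0788198
  1.0040000    0.4303901
  0.3008000    0.6795592
SHELL S 1
  0.3008000    1.0000000
SHELL P 4
  17.7000000   0.0430180
  3.8540000    0.2289130
  1.0460000    0.5087280
  0.2753000    0.4605300
SHELL P 1
  0.2753000    1.0000000
SHELL D 1
  1.1850000    1.0000000
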