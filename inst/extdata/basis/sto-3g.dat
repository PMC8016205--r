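# STO-3G minimal basis (H, C, N, O)
# format: ELEMENT <symbol>; SHELL <L> <nprim>; then nprim lines "exponent coefficient"
ELEMENT H
SHELL S 3
  3.42525091   0.15432897
  0.62391373   0.53532814
  0.16885540   0.44463454
ELEMENT C
SHELL S 3
  71.61683735  0.15432897
  13.04509632  0.53532814
  3.53051216   0.44463454
SHELL S 3
  2.94124936  -0.09996723
  0.68348310   0.39951283
  0.22228997   0.70011547
SHELL P 3
  2.94124936   0.15591627
  0.68348310   0.60768372
  0.22228997   0.39195739
ELEMENT N
SHELL S 3
  99.10616896  0.15432897
  18.05231239  0.53532814
  4.88566024   0.44463454
SHELL S 3
  3.78045559  -0.09996723
  0.87849664   0.39951283
  0.28571437   0.70011547
SHELL P 3
  3.78045559   0.15591627
  0.87849664   0.60768372
  0.28571437   0.39195739
ELEMENT O
SHELL S 3
  130.70932140 0.15432897
  23.80886605  0.53532814
  6.44360831   0.44463454
SHELL S 3
  5.03315132  -0.09996723
  1.16959612   0.39951283
  0.38038896   0.70011547
SHELL P 3
  5.03315132   0.15591627
  1.16959612   0.60768372
  0.38038896   0.39195739
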