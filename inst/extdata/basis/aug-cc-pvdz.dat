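# Diffuse augmentation of cc-pvdz (H, C, N, O).
AUGMENT cc-pvdz
ELEMENT H
SHELL S 1
  0.0297400    1.0000000
SHELL P 1
  0.1410000    1.0000000
ELEMENT C
SHELL S 1
  0.0469000    1.0000000
SHELL P 1
  0.0404100    1.0000000
SHELL D 1
  0.1510000    1.0000000
ELEMENT N
SHELL S 1
  0.0612400    1.0000000
SHELL P 1
  0.0561100    1.0000000
SHELL D 1
  0.2300000    1.0000000
ELEMENT O
SHELL S 1
  0.0789600    1.0000000
SHELL P 1
  0.0685600    1.0000000
SHELL D 1
  0.3320000    1.0000000
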