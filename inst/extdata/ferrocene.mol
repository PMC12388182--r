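ferrocene
  zobmol  2D

 11 20  0  0  0  0  0  0  0  0999 V2000
    1.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.3090    0.9511    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8090    0.5878    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8090   -0.5878    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.3090   -0.9511    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.0000    3.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.3090    3.9511    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8090    3.5878    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8090    2.4122    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.3090    2.0489    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    1.5000    0.0000 Fe  0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  2  0
  3  4  1  0
  4  5  2  0
  5  1  1  0
  1 11  1  0
  2 11  0  0
  3 11  0  0
  4 11  0  0
  5 11  0  0
  6  7  1  0
  7  8  2  0
  8  9  1  0
  9 10  2  0
 10  6  1  0
  6 11  1  0
  7 11  0  0
  8 11  0  0
  9 11  0  0
 10 11  0  0
M  ZHC  1  11   0
M  END
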