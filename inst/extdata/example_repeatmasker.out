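   SW  perc perc perc  query     position in query           matching repeat         position in repeat
score  div. del. ins.  sequence  begin end (left)  strand  repeat       class/family  begin end (left) ID

 2103  12.1  0.4  1.2  read_001   1201  1700  (700)  +      IAPEz-int    LTR/ERV2       1  500  (4800)   1
  480  18.9  2.0  0.5  read_001   1701  1890  (510)  C      B2_Mm2       SINE/B2        1  190  (0)       2
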