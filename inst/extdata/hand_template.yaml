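frame:
- 899
- 1312
finger_lengths:
- 211.377375
- 294.64725
- 320.26875
- 301.052625
- 243.40425
finger_widths:
- 73.6281
- 59.46885
- 59.46885
- 56.637
- 50.9733
points:
- point: V1
  row: 221.766375
  col: 480.9253
- point: V2
  row: 138.4965
  col: 571.5445
- point: V3
  row: 112.875
  col: 656.5
- point: V4
  row: 132.091125
  col: 735.7918
- point: V5
  row: 189.7395
  col: 812.25175
- point: V6
  row: 665.76
  col: 656.5
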