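bone_age,pct_mature
8.0,82.6
8.5,83.8
9.0,85.0
9.5,86.1
10.0,87.0
10.5,88.2
11.0,89.4
11.5,90.5
12.0,91.7
12.5,93.0
13.0,94.3
13.5,95.5
14.0,96.7
14.5,97.8
15.0,98.8
15.5,99.5
16.0,99.9
17.0,100.0
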