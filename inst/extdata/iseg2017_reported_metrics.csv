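infant,precision,recall,f1,accuracy
4,0.910571,0.906693,0.907219,0.906731
7,0.915163,0.914503,0.914542,0.915281
2,0.917713,0.917772,0.917736,0.917950
5,0.919483,0.918829,0.918891,0.918972
10,0.922817,0.921393,0.921721,0.921573
9,0.923732,0.922788,0.922694,0.922976
3,0.927507,0.927406,0.927385,0.927496
6,0.928836,0.928748,0.928642,0.928893
1,0.929377,0.929290,0.929122,0.929426
8,0.932538,0.932624,0.932568,0.932671
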