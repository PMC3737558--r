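"V1","V2","V3"
1,0,1
-1,1.22464679914735e-16,0
0.5,0.866025403784439,-1
-0.5,-0.866025403784438,1
-0.5,0.866025403784439,0
0.5,-0.866025403784439,-1
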