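disease,markerA_cut1,markerA_cut2,markerB_cut1,markerB_cut2
1,1,1,1,1
1,1,1,1,0
1,1,1,1,1
1,1,0,1,1
1,1,1,1,1
1,1,1,1,1
1,1,1,0,1
1,1,0,1,1
1,1,1,1,0
1,1,1,1,1
1,1,1,1,1
1,1,1,1,1
1,1,1,1,1
1,1,1,1,1
1,1,1,1,1
1,1,1,1,1
1,1,1,1,1
1,1,1,1,1
1,1,1,1,1
1,1,1,1,1
1,1,1,1,1
1,1,1,1,1
1,1,1,1,1
1,1,1,1,1
1,1,1,1,1
1,1,1,1,0
1,1,1,0,1
1,1,1,1,1
1,1,1,1,1
1,1,1,0,1
0,1,0,0,1
0,0,1,0,0
0,0,0,0,1
0,0,0,0,0
0,0,1,1,1
0,0,0,0,1
0,0,0,0,1
0,0,1,0,1
0,1,0,0,0
0,1,0,0,1
0,0,0,0,0
0,0,0,0,1
0,0,1,0,1
0,0,0,0,1
0,0,0,0,0
0,0,1,0,0
0,0,0,0,0
0,0,1,1,0
0,0,0,0,1
0,0,0,0,1
0,0,0,1,0
0,0,0,0,0
0,0,1,0,0
0,0,0,1,0
0,0,0,0,0
0,1,1,0,1
0,0,0,1,1
0,0,0,1,0
0,0,1,0,1
0,0,1,0,0
0,0,0,0,0
0,0,0,1,1
0,1,0,0,1
0,0,0,0,1
0,0,0,0,0
0,0,0,0,1
0,0,0,0,0
0,0,1,1,0
0,0,0,1,1
0,0,1,1,1
0,0,0,0,1
0,0,0,0,0
0,0,0,0,1
0,0,0,1,0
0,0,0,0,1
0,0,0,0,1
0,0,0,0,0
0,0,0,0,1
0,0,0,0,1
0,0,0,0,0
0,0,0,0,0
0,0,0,0,0
0,0,0,0,1
0,0,0,0,0
0,0,0,0,0
0,0,0,0,1
0,0,0,0,0
0,0,0,0,0
0,0,1,0,0
0,0,1,0,0
0,0,0,0,0
0,1,0,0,1
0,0,0,0,0
0,0,0,0,0
0,0,0,0,1
0,1,0,0,0
0,0,0,0,0
0,0,0,0,1
0,0,0,0,1
0,0,1,0,1
0,0,0,0,1
0,0,0,1,0
0,0,0,0,1
0,0,0,0,0
0,0,0,0,0
0,0,0,0,0
0,0,1,0,0
0,0,1,0,0
0,0,1,0,0
0,1,0,0,0
0,1,1,0,0
0,0,1,0,0
0,0,1,0,0
0,0,0,0,0
0,0,0,0,0
0,0,0,0,0
0,0,1,0,0
0,0,0,0,1
0,0,1,1,0
0,0,0,0,1
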