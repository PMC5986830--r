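label dataset sw sf
15N 1H
golden.nv
{2000.0 8000.0}
{60.8 600.1}
 15N.L 15N.P 15N.W 15N.B 1H.L 1H.P 1H.W 1H.B vol int stat comment flag0
0 {103.T.N} 110.112 0.050 0.050 {103.T.H} 8.221 0.010 0.010 3.4e7 1.2e7 0 {?} 0
1 {45.G.N} 108.500 0.050 0.050 {45.G.H} 8.903 0.010 0.010 2.1e7 9.0e6 0 {?} 0
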