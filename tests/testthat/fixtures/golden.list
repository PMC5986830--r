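       Assignment         w1         w2        Height        Volume

          T103N-H    110.112      8.221  1.200000e+07  3.400000e+07
           G45N-H    108.500      8.903  9.000000e+06  2.100000e+07
     N57ND2a-HD2a    112.510      7.110  5.000000e+06  1.250000e+07
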