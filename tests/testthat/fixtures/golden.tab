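REMARK synthetic 2D peak table
VARS   INDEX X_PPM Y_PPM XW_HZ YW_HZ HEIGHT VOL ASS
FORMAT %5d %9.3f %9.3f %8.2f %8.2f %+e %+e %s
    1     8.221   110.112    20.50    18.00 +1.200000e+07 +3.400000e+07 T103N-H
    2     8.903   108.500    21.00    19.00 +9.000000e+06 +2.100000e+07 G45N-H
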