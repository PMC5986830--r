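Number,Position F1,Position F2,Assign F1,Assign F2,Line Width F1 (Hz),Line Width F2 (Hz),Height,Volume,Merit,Details,Fit Method
1,110.112,8.221,Thr103N,Thr103H,18.00,20.50,1.2e7,3.4e7,1.0,alt assignment 48R,parabolic
2,108.500,8.903,Gly45N,Gly45H,,,9.0e6,2.1e7,0.5,,gaussian
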