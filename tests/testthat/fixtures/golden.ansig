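ANSIG v3.3 export crosspeaks
    1  110.112    8.221  T 103 N  H
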