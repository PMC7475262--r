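h_col	58
c_col	112
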