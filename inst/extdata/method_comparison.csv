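reference_pct,comparison_pct,this_method_pct
99,98,97
97,98,97
95,99,94
98,98,98
97,98,98
96,97,96
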