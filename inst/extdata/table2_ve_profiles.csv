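example,stratum_label,ve_s,ve_sh
Example 1,Recent,0.90,0.97
Example 1,Longer ago,0.65,0.80
Example 2,Recent,0.62,0.86
Example 2,Longer ago,0.00,0.71
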