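interval,selected,pool
T1,182.4,33736
T2,92.8,32378
T3,44.8,33886
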