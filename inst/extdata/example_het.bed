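chr4	48200000	49500000
chr4	51000000	52700000
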