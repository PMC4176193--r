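arm_id	chrom	arm	noncritical_start	noncritical_end	critical_start	gap_start	gap_end	provenance
4p	chr4	p	45300000	48200000	45000000	45000000	45300000	synthetic demo map
4q	chr4	q	52700000	61400000	61500000	61400000	61500000	synthetic demo map
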