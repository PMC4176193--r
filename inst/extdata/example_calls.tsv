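case_id	probe_name	chrom	start	end	arm	signal	structure_hint	n_metaphases_with_marker	n_metaphases_total
case_A	RP11-178N2	chr4	45556237	45736237	p	single	ring	14	16
case_A	RP11-89F4	chr4	44621297	44801297	p	absent	ring	14	16
case_A	RP11-91C3	chr4	61086318	61266318	q	single	ring	14	16
case_A	RP11-63E13	chr4	66420553	66600553	q	absent	ring	14	16
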