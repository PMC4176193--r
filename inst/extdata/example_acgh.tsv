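chrom	start	end	mean_log2	boundary_start	boundary_end
chr4	45754992	53000000	0.52	45518972	45754992
chr4	53000000	61126608	0.52	61126608	61343360
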