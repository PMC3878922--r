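clone	chrom	start	end	event	validated_by
clone-3	chr15	32983895	33026044	gain	Q,S
clone-3	chr19	23000913	23338557	gain	Q,S,B
clone-3	chr32	41654990	41731424	gain	Q,S
clone-3	chrX	1401988	6598355	gain	Q,S,B
clone-6	chr2	71652481	71688546	loss	Q
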