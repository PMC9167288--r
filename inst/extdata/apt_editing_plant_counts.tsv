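sample_id	experiment	n_snv	n_indel	excluded
Control#1	control	0	0	FALSE
Control#2	control	0	3	FALSE
PEG#1	peg	20	19	FALSE
PEG#2	peg	10	19	FALSE
PEG-DNA#1	peg_dna	16	24	FALSE
PEG-DNA#2	peg_dna	NA	NA	TRUE
CRIS1#1	crispr	9	16	FALSE
CRIS1#2	crispr	11	20	FALSE
CRIS2#1	crispr	6	29	FALSE
CRIS2#2	crispr	7	13	FALSE
TAL#1	talen	21	31	FALSE
TAL#2	talen	11	33	FALSE
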