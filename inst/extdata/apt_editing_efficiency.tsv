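strategy	regenerants	resistant
CRISPR-Cas (sgRNA#1)	71100	1718
CRISPR-Cas (sgRNA#2)	61600	2077
TALEN (402+405)	68300	56
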