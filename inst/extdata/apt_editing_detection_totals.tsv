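var_type	n_detected
SNV	5184
InDel	4182
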