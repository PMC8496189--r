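scope	sequenced	low_read_count	low_actb	n_conditions
dataset	4734	888	159	12
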