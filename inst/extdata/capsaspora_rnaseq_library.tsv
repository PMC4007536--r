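metric	value
total_rnaseq_reads	394576834
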