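id	cds_start	cds_end	exon_lengths
HES7_synthetic	101	775	180,330,220,345
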