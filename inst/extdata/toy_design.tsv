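sample_id	specimen_id	replicate	kit	is_control	sample_type	dilution
spA_r1	spA	1	K1	FALSE	oral	NA
spA_r2	spA	2	K1	FALSE	oral	NA
spB_r1	spB	1	K1	FALSE	oral	NA
spB_r2	spB	2	K1	FALSE	oral	NA
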