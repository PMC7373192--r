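specimen_id	copies
spA	1e6
spB	5e4
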