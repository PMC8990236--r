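animal	ho_count	he_count	homology_published
cow	7762707	11408849	99.501
fetus	7734830	11537221	99.500
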