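tas_rel	growth_dir	significant	expected_call
higher	faster	yes	oncogenic
higher	faster	no	likely_oncogenic
higher	slower	yes	likely_oncogenic
higher	slower	no	likely_oncogenic
equal	faster	yes	neutral
equal	faster	no	neutral
equal	slower	yes	neutral
equal	slower	no	neutral
lower	faster	yes	likely_LoF
lower	faster	no	likely_LoF
lower	slower	yes	LoF
lower	slower	no	likely_LoF
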