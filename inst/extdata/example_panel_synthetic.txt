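# Synthetic placeholder CIMP panel (format example: one CpG id per line).
# The study-scale panel holds 1293 promoter-enriched CpG sites and is not
# redistributed here; generate_cohort() emits matched synthetic panels.
cg0000042
cg0000137
cg0000256
cg0000391
cg0000518
cg0000644
cg0000777
cg0000892
cg0000963
cg0001024
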