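OTU_ID	sample_A	sample_B
OTU_000001	3	2
OTU_000002	1	0
OTU_000003	0	2
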