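id	label	planted_k	planted_l
pos_001	1	96	99
pos_002	1	141	146
pos_003	1	22	28
pos_004	1	14	18
pos_005	1	116	119
neg_001	0	NA	NA
neg_002	0	NA	NA
neg_003	0	NA	NA
neg_004	0	NA	NA
neg_005	0	NA	NA
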