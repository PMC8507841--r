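secretion_type	n_clusters
T1	13
T2	20
T3	2
T5	8
T6	27
other	4
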