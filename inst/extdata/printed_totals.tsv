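quantity	value
abundant_transporters_total	124
transporter_clusters_total	1149
tigr_linked_clusters	338
assembly_orfs_total	6757106
transporter_orfs_assembly	66029
secretion_clusters_total	74
tcdb_residual_printed_pct	15
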