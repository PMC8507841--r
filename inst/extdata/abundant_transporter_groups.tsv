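transport_group	n_clusters
nutrient_importer	59
exporter_utility_secretion	25
exporter_toxin_secretion	21
other_transport	10
metal_transport	9
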