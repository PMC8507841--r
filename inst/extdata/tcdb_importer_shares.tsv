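tcdb_class	share_pct	major
2A	43	TRUE
3A	42	TRUE
1A	5	FALSE
1B	2	FALSE
2C	1	FALSE
3D	4	FALSE
4A	2	FALSE
4B	2	FALSE
9A	1	FALSE
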