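# Per-biome metagenome homolog counts and reference-database counts for
# unsolved protein families used in the homolog-supplementation example.
# Columns: family, reference_count, then one column per biome.
family	reference_count	Soil	Freshwater	Gut	Engineered
PF12597	182	183	125	39	68
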