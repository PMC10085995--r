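# GO annotations retrieved from the four-biome metagenome cohort, per
# namespace; total = sum of the three namespaces.
namespace	n_terms
biological_process	421
cellular_component	284
molecular_function	140
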