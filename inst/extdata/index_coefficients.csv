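trait,coefficient
main_stem_length,0.055
n_nodes,0.0053
days_to_flowering,0.0011
n_flower_clusters,0.0728
n_primary_branches,0.0015
seed_weight_1000,-1e-04
test_weight,0.0306
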