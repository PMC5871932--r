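trait,main_stem_length,n_nodes,days_to_flowering,n_flower_clusters,n_primary_branches,seed_weight_1000,test_weight
main_stem_length,1,0.56,0.4,0.36,0.1,0.16,0.13
n_nodes,0.56,1,0.27,0.46,0.16,0.03,0.26
days_to_flowering,0.4,0.27,1,0.26,0.09,-0.04,0.09
n_flower_clusters,0.36,0.46,0.26,1,0.4,0.04,0.31
n_primary_branches,0.1,0.16,0.09,0.4,1,-0.02,0.19
seed_weight_1000,0.16,0.03,-0.04,0.04,-0.02,1,0.24
test_weight,0.13,0.26,0.09,0.31,0.19,0.24,1
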