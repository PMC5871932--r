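trait,seed_yield,main_stem_length,n_nodes,days_to_flowering,n_flower_clusters,n_primary_branches,seed_weight_1000,test_weight
seed_yield,1,0.74,0.85,0.05,0.66,0.52,-0.22,0.47
main_stem_length,0.74,1,0.85,0.16,0.53,0.41,0.13,0.4
n_nodes,0.85,0.85,1,0.12,0.75,0.64,-0.22,0.27
days_to_flowering,0.05,0.16,0.12,1,0.18,0.23,0.54,0.07
n_flower_clusters,0.66,0.53,0.75,0.18,1,0.73,-0.13,0.03
n_primary_branches,0.52,0.41,0.64,0.23,0.73,1,-0.37,-0.43
seed_weight_1000,-0.22,0.13,-0.22,0.54,-0.13,-0.37,1,0.22
test_weight,0.47,0.4,0.27,0.07,0.03,-0.43,0.22,1
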