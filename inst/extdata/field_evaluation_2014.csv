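population,scheme,cycle,n,trait,mean,sd
initial,both,0,34,main_stem_length,100.5,17.72
initial,both,0,34,n_nodes,11.15,1.44
initial,both,0,34,days_to_flowering,20.41,1.23
initial,both,0,34,n_flower_clusters,69.91,23.78
initial,both,0,34,n_primary_branches,4.44,0.93
initial,both,0,34,seed_weight_1000,29.27,2.83
initial,both,0,34,test_weight,565.92,61.19
initial,both,0,34,n_secondary_branches,7.41,2.91
initial,both,0,34,n_seeds_per_plant,407.68,181.6
initial,both,0,34,selection_index,28.35,3.09
post_gs1_ps1,both,1,30,main_stem_length,112.2,14.16
post_gs1_ps1,both,1,30,n_nodes,11.87,1.5
post_gs1_ps1,both,1,30,days_to_flowering,21.27,0.98
post_gs1_ps1,both,1,30,n_flower_clusters,82.7,29.07
post_gs1_ps1,both,1,30,n_primary_branches,4.47,0.97
post_gs1_ps1,both,1,30,seed_weight_1000,29.27,3.1
post_gs1_ps1,both,1,30,test_weight,576.42,47.24
post_gs1_ps1,both,1,30,n_secondary_branches,7.97,2.3
post_gs1_ps1,both,1,30,n_seeds_per_plant,452.33,173.99
post_gs1_ps1,both,1,30,selection_index,29.92,3.34
post_gs2,gs,2,31,main_stem_length,117.74,15.28
post_gs2,gs,2,31,n_nodes,12.35,1.3
post_gs2,gs,2,31,days_to_flowering,21.61,1.56
post_gs2,gs,2,31,n_flower_clusters,84.52,25.19
post_gs2,gs,2,31,n_primary_branches,4.55,0.99
post_gs2,gs,2,31,seed_weight_1000,30.39,3.79
post_gs2,gs,2,31,test_weight,616.43,46.43
post_gs2,gs,2,31,n_secondary_branches,8.16,2.63
post_gs2,gs,2,31,n_seeds_per_plant,454.52,137.11
post_gs2,gs,2,31,selection_index,31.58,2.81
post_ps2,ps,2,34,main_stem_length,117.91,14.63
post_ps2,ps,2,34,n_nodes,12.18,1.29
post_ps2,ps,2,34,days_to_flowering,21.15,0.86
post_ps2,ps,2,34,n_flower_clusters,90.12,22.37
post_ps2,ps,2,34,n_primary_branches,4.74,0.96
post_ps2,ps,2,34,seed_weight_1000,29.6,2.92
post_ps2,ps,2,34,test_weight,617.8,26.58
post_ps2,ps,2,34,n_secondary_branches,8.03,2.12
post_ps2,ps,2,34,n_seeds_per_plant,524.94,147.04
post_ps2,ps,2,34,selection_index,32.04,2.31
post_gs3,gs,3,34,main_stem_length,125.29,16.77
post_gs3,gs,3,34,n_nodes,12.47,1.35
post_gs3,gs,3,34,days_to_flowering,21.91,1.38
post_gs3,gs,3,34,n_flower_clusters,101.29,24.75
post_gs3,gs,3,34,n_primary_branches,4.82,0.9
post_gs3,gs,3,34,seed_weight_1000,28.37,3.41
post_gs3,gs,3,34,test_weight,600.67,49.37
post_gs3,gs,3,34,n_secondary_branches,9,2.7
post_gs3,gs,3,34,n_seeds_per_plant,562.24,137.7
post_gs3,gs,3,34,selection_index,32.74,2.25
post_gs4,gs,4,35,main_stem_length,133.14,14.58
post_gs4,gs,4,35,n_nodes,12.94,1.28
post_gs4,gs,4,35,days_to_flowering,22.31,1.43
post_gs4,gs,4,35,n_flower_clusters,100.94,31.01
post_gs4,gs,4,35,n_primary_branches,4.6,1.06
post_gs4,gs,4,35,seed_weight_1000,30.28,2.7
post_gs4,gs,4,35,test_weight,593.85,49
post_gs4,gs,4,35,n_secondary_branches,8.23,1.78
post_gs4,gs,4,35,n_seeds_per_plant,539,166.49
post_gs4,gs,4,35,selection_index,32.9,3.45
post_ps3,ps,3,35,main_stem_length,119.17,12.46
post_ps3,ps,3,35,n_nodes,12.06,1.64
post_ps3,ps,3,35,days_to_flowering,21.4,2.74
post_ps3,ps,3,35,n_flower_clusters,98.57,34.04
post_ps3,ps,3,35,n_primary_branches,4.74,1.15
post_ps3,ps,3,35,seed_weight_1000,29.91,3.82
post_ps3,ps,3,35,test_weight,613.63,51.47
post_ps3,ps,3,35,n_secondary_branches,9,2.39
post_ps3,ps,3,35,n_seeds_per_plant,515.94,115.81
post_ps3,ps,3,35,selection_index,32.6,2.74
post_gs5,gs,5,35,main_stem_length,130.89,17.82
post_gs5,gs,5,35,n_nodes,13.26,1.46
post_gs5,gs,5,35,days_to_flowering,21.91,1.29
post_gs5,gs,5,35,n_flower_clusters,123.51,35.42
post_gs5,gs,5,35,n_primary_branches,4.31,0.87
post_gs5,gs,5,35,seed_weight_1000,29.49,3.13
post_gs5,gs,5,35,test_weight,611.2,46.57
post_gs5,gs,5,35,n_secondary_branches,9.37,1.96
post_gs5,gs,5,35,n_seeds_per_plant,556.4,170.56
post_gs5,gs,5,35,selection_index,34.99,3.49
post_gs6,gs,6,33,main_stem_length,129.21,16.37
post_gs6,gs,6,33,n_nodes,13.67,1.55
post_gs6,gs,6,33,days_to_flowering,22.06,2.01
post_gs6,gs,6,33,n_flower_clusters,114.42,28.73
post_gs6,gs,6,33,n_primary_branches,4.85,0.83
post_gs6,gs,6,33,seed_weight_1000,28.46,2.93
post_gs6,gs,6,33,test_weight,612.75,44.11
post_gs6,gs,6,33,n_secondary_branches,9.21,2.52
post_gs6,gs,6,33,n_seeds_per_plant,588.21,167.63
post_gs6,gs,6,33,selection_index,34.29,3.12
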