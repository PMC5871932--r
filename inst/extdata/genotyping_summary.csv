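name,value
candidate_markers_gs1,274303
markers_gs1,50000
markers_gs2,11480
markers_total_after_year1,14598
markers_gs3,6373
markers_gs4,6225
markers_gs5,4614
markers_gs6,4417
mapped_markers,1511
map_loci,756
polymorphic_map_loci,492
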