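# Published per-target Top-10 hit-rate triples (a = Acceptable-or-higher,
# b = Medium-or-higher, c = High) of seven complex-QA scoring methods on the
# DBM55-AF2 benchmark, plus each target's best-possible triple, transcribed
# from the benchmark's published results table.
target_id,dproqa_a,dproqa_b,dproqa_c,dproqa_gt_a,dproqa_gt_b,dproqa_gt_c,dproqa_gte_a,dproqa_gte_b,dproqa_gte_c,dproqa_gtn_a,dproqa_gtn_b,dproqa_gtn_c,zrank2_a,zrank2_b,zrank2_c,goap_a,goap_b,goap_c,gnn_dove_a,gnn_dove_b,gnn_dove_c,best_a,best_b,best_c
6AL0,9,2,0,10,0,0,10,0,0,10,2,0,9,0,0,9,0,0,6,0,0,10,2,0
3SE8,8,8,0,9,9,0,8,8,0,8,8,0,2,2,0,8,8,0,4,3,0,10,10,0
5GRJ,10,10,0,9,9,0,10,10,0,9,9,0,5,4,0,10,9,0,6,6,0,10,10,0
6A77,7,7,0,7,7,0,8,8,0,8,8,0,4,4,0,3,3,0,3,3,0,8,8,0
4M5Z,10,10,1,10,10,0,10,10,0,10,10,0,10,10,1,10,10,1,10,10,0,10,10,1
4ETQ,1,1,0,1,1,0,1,1,0,1,1,0,1,1,0,1,1,0,0,0,0,1,1,0
5CBA,10,10,1,10,10,0,10,10,0,10,10,1,10,10,4,10,10,2,10,10,3,10,10,6
5WK3,0,0,0,0,0,0,0,0,0,0,0,0,3,0,0,0,0,0,0,0,0,3,0,0
5Y9J,4,0,0,6,0,0,5,0,0,4,0,0,5,0,0,5,0,0,2,0,0,8,0,0
6BOS,10,10,0,10,10,0,10,10,0,10,10,0,10,10,0,10,10,0,10,10,0,10,10,0
5HGG,8,0,0,8,0,0,8,0,0,8,0,0,10,0,0,10,0,0,10,0,0,10,0,0
6A0Z,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0,3,0,0
3U7Y,2,2,1,2,2,1,2,2,1,2,1,0,1,1,1,2,2,1,2,2,1,2,2,1
3WD5,10,8,0,9,8,0,9,8,0,9,8,0,6,4,0,10,8,0,8,6,0,10,10,0
5KOV,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,2,0,0
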