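# Published per-target DockQ ranking losses of seven complex-QA scoring
# methods on the DBM55-AF2 benchmark (15 targets, AlphaFold-Multimer decoys
# of Docking Benchmark 5.5 complexes), transcribed from the benchmark's
# published results table.
target_id,dproqa,dproqa_gt,dproqa_gte,dproqa_gtn,zrank2,goap,gnn_dove
6AL0,0.0,0.156,0.156,0.0,0.345,0.331,0.382
3SE8,0.079,0.041,0.041,0.079,0.735,0.0,0.408
5GRJ,0.024,0.012,0.095,0.012,0.774,0.23,0.595
6A77,0.037,0.062,0.0,0.037,0.583,0.59,0.589
4M5Z,0.015,0.026,0.026,0.015,0.221,0.133,0.269
4ETQ,0.0,0.76,0.0,0.748,0.759,0.0,0.748
5CBA,0.052,0.038,0.052,0.058,0.047,0.007,0.047
5WK3,0.114,0.114,0.114,0.186,0.0,0.109,0.109
5Y9J,0.0,0.0,0.0,0.0,0.202,0.0,0.423
6BOS,0.081,0.081,0.0,0.0,0.087,0.09,0.053
5HGG,0.051,0.051,0.121,0.051,0.051,0.051,0.047
6A0Z,0.207,0.207,0.207,0.207,0.218,0.214,0.206
3U7Y,0.0,0.021,0.0,0.0,0.772,0.0,0.021
3WD5,0.011,0.011,0.011,0.0,0.704,0.011,0.666
5KOV,0.065,0.08,0.085,0.087,0.008,0.078,0.083
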