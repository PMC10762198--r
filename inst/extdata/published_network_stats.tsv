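quantity	value
n_samples	397
initial_nodes	5457
initial_edges	31966
initial_positive	30657
initial_negative	1309
initial_positive_pct_printed	95.9
static_nodes	5448
static_edges	29118
static_positive	28178
static_negative	940
static_positive_pct_printed	96.8
static_negative_pct_printed	3.2
srf_basin_assoc_absent_in_ms	14971
srf_present	18234
ms_absence_pct_printed	82.1
mst_nodes	397
mst_edges	396
n_clusters	36
surface_dominated_clusters	13
surface_dominated_pct_printed	36.1
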