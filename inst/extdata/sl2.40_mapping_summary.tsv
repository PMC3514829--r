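key	value
total_reads	93682
unique_pair_ends	28804
unique_ends	8263
repeat_reads	43598
redundant_reads	10943
weak_reads	2015
no_hit_reads	59
n_clones	55296
mean_insert_bp	101300
median_insert_bp	101800
genome_size_bp	950000000
insert_modal_bin_count	6396
insert_mapped_clones	14101
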