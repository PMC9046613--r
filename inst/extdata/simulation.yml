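# Reference simulation condition.
#
# Integration parameters reflect reported characteristics of AAV/vector
# integration: 100 integrations per replicate, sub-genomic probability 0.5 with a
# 50 bp minimum fragment length, rearrangement and deletion
# probabilities 0.1 with Poisson(1) piece counts, gap and overlap
# probabilities 0.2 with Poisson(1) junction lengths, host-deletion
# probability 0.2 with Poisson(20) lengths. Spacing, episome and read
# parameters are package defaults. Any parameter may instead be a list
# of values; the Cartesian product defines the condition grid.

host_fasta: host.fa
virus_fasta: virus.fa
out_dir: sim_out
global_seed: 1
replicates: 2

n_ints: 100
min_sep: 1000
p_whole: 0.5
min_len: 50
max_len: 2000
p_rearrange: 0.1
p_delete: 0.1
lambda_split: 1
p_gap: 0.2
p_overlap: 0.2
lambda_junction: 1
p_host_deletion: 0.2
lambda_host_deletion: 20
epi_num: 2

read_len: 150
coverage: 5
frag_mean: 500
frag_sd: 30
error_rate_start: 0.001
error_rate_end: 0.01
min_flank: 1
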