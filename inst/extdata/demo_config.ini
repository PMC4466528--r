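# Demo configuration for the ghrecover command-line front end.
# [defaults] holds pipeline thresholds (pipeline_config keys);
# [simulate] holds simulator settings (sim_config keys).

[defaults]
recruit_evalue_max = 1e-2
min_overlap_len = 40
min_overlap_identity = 0.90
min_contig_len = 1000
rng_seed = 47

[simulate]
n_genomes = 2
genome_len = 6000
genes_per_genome = 1
sample_names = Z7,Z8
reads_per_sample = 700,700
read_len_mean = 300
read_len_sd = 50
subst_rate = 0.002
homopolymer_indel_rate = 0.005
rng_seed = 47
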