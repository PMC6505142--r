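# Example Monte Carlo scenario: additive trait, three loci in mutual
# but imperfect LD, interaction between the two markers tested at 0.05.
id: example_mutual_ld
model: additive
sample_size: 10000
qtl_variance_fraction: 0.01
qtl_index: 1          # locus order in ld_spec: z, x1, x2
marker_indices: [2, 3]
alpha: 0.05
replicates: 200
master_seed: 42
ld_spec:
  allele_freqs: [0.5, 0.4, 0.3]
  pairwise_D: [0.05, 0.04, 0.03]   # D(z,x1), D(z,x2), D(x1,x2)
  three_locus_D: 0.01
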