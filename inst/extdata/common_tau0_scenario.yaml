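# Two common causal SNPs in linkage equilibrium (haplotype frequencies
# 0.10/0.30/0.15/0.45), strictly additive effects with haplotype variance
# 0.006; additive model fitted at the suggestive regional threshold.
system: common_tau0_system.tsv
n: 5000
n_replicates: 1000
models: [additive]
alpha: 5.0e-5
seed: 1
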