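{"n_samples":60,"target_fraction":0.3,"co_mutation_prob":0.05,"restart_prob":0.05,"max_target_edges":10,"max_target_genes":20,"background_counts":{"dist":"nbinom","rate_per_gene":0.005,"size":5,"mean":null},"perturbation":{"mode":"none","fraction":0},"rng_seed":2024}
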