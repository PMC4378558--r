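# Shipped default L-score feature weights, per peak-pair-count group.
# Trained by per-group logistic regression on annotated Salmonella
# typhimurium CID envelope matches; group 2 carries no missing-peak weight
# (group-2 envelopes contain no missing peaks).
2.mz_dist = 3.237
2.int_dist = 0.851
2.n_support = -1.517
2.n_loss = -2.491
3.mz_dist = 4.987
3.int_dist = 1.565
3.n_support = -1.471
3.n_loss = -0.810
3.n_missing = 0.277
4.mz_dist = 3.942
4.int_dist = 1.448
4.n_support = -1.958
4.n_loss = -0.795
4.n_missing = 0.386
5+.mz_dist = 3.820
5+.int_dist = 1.349
5+.n_support = -0.992
5+.n_loss = -0.343
5+.n_missing = 0.096
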