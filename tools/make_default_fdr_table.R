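#!/usr/bin/env Rscript
# Regenerates inst/extdata/lscore_fdr_synthetic.tsv, the shipped default
# local-FDR lookup table. It is trained on SYNTHETIC data: candidates
# enumerated from simulated spectra (overlapping multi-charge averagine
# envelopes, ground-truth labels from the planted masses), scored with the
# shipped default weights. Fully deterministic; rerun from the repository
# root after changing the simulator or the candidate pipeline.
library(ldeconv)

set.seed(761394)
matches <- list()
for (i in seq_len(40)) {
  sim <- simulate_spectrum(sim_config(n_ions = 40))
  cand <- annotate_support(generate_candidates(sim$spectrum,
                                               max_charge = 24))
  matches <- c(matches, label_matches(cand, sim$truth$mass))
}
message(length(matches), " labeled envelope matches")
labeled <- matches_to_table(matches)
tab <- build_fdr_table(labeled, default_weights())
write_fdr_table(tab, file.path("inst", "extdata",
                               "lscore_fdr_synthetic.tsv"))
message("written inst/extdata/lscore_fdr_synthetic.tsv")
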