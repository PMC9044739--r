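#!/usr/bin/env Rscript
# Stage 4: the exhaustive panel search. Every 1..k_max-plex protein
# combination (plus PSA) is scored by paired bootstrapped cross-validated
# random forests; models are ranked by median fold AUC; the set of models
# statistically indistinguishable from the best (paired t, Bonferroni)
# yields the feature-prevalence table that nominates the final panel.
source("analysis/config.R")

m <- run_pipeline(study_config, stages = "search")
cat(sprintf("searched %d models; best: %s (median AUC %.3f)\n",
            m$summary$n_models, m$summary$best_model,
            m$summary$best_median_auc))
cat(sprintf("equivalence set: %d models; top prevalence features: %s\n",
            m$summary$equivalence_set_size,
            paste(unlist(m$summary$top_features), collapse = ", ")))
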