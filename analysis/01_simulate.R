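#!/usr/bin/env Rscript
# Stage 1: simulate the serum cohort — patient covariates with recurrence
# follow-up plus the transition-level PRM report with a spike-in
# reference, batch factors, and MNAR/MCAR missingness.
source("analysis/config.R")

m <- run_pipeline(study_config, stages = "simulate")
cat(sprintf("simulated %d patients (%d recurrence events) -> %s\n",
            m$summary$n_patients, m$summary$n_events,
            file.path(study_config$outdir, "transitions.tsv")))
truth <- jsonlite::read_json(file.path(study_config$outdir, "truth.json"),
                             simplifyVector = TRUE)
cat("planted informative proteins:",
    paste(truth$informative_protein_ids, collapse = ", "), "\n")
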