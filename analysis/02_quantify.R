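#!/usr/bin/env Rscript
# Stage 2: transition-level report -> protein quantity matrix. Precursors
# are the summed area of their four most prominent transitions, proteins
# the sum of their precursors, and every quantity is divided by the
# sample's bovine A1AG spike-in to cancel processing variation.
source("analysis/config.R")

m <- run_pipeline(study_config, stages = "quantify")
cat(sprintf("quantified %d candidate proteins -> %s\n",
            m$summary$n_proteins_quantified,
            file.path(study_config$outdir, "protein_matrix.tsv")))
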