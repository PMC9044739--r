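# Shared configuration for the numbered analysis drivers. One global seed
# fixes the whole study; every stage writes its tables under results/.
#
# Study scale: a PRM-sized cohort (78 patients, ~40% biochemical
# recurrence) with 12 candidate serum proteins of which two are planted as
# informative (1 log2 unit lower in recurrence cases), searched
# exhaustively up to 3-plex panels under 20 paired bootstrap folds with
# 100-tree forests.

library(prmstrat)

study_config <- pipeline_config(
  outdir = "results",
  seed = 42,
  sim = list(n_patients = 78, n_proteins = 12, n_informative = 2,
             effect_log2 = 1, recurrence_rate = 0.4),
  search = list(k_max = 3, n_folds = 20, n_trees = 100,
                base_features = "psa"),
  fit = list(n_markers = 2, base = c("psa", "gleason"), n_trees = 200)
)
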