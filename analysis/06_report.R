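#!/usr/bin/env Rscript
# Stage 6: human-readable run report, rendered purely from the manifest.
source("analysis/config.R")

lines <- write_report(file.path(study_config$outdir, "manifest.json"),
                      file.path(study_config$outdir, "report.txt"))
writeLines(lines)
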