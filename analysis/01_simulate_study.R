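#!/usr/bin/env Rscript
# Stage 1: generate the synthetic multi-platform study.
#
# Emulates a four-dataset blood miRNA microarray study: 850 measured
# features per platform (half shared across platforms), group sizes
# 20/21, 59/37, 23/70 and 8/8 (case/control), and planted signals — 18
# directionally consistent consensus features, 21 features significant in
# >= 3 datasets with conflicting directions, and 60 sporadic features.
# Writes every file the later stages read, plus the ground truth.

library(mirnetcons)

out <- "results/study"
spec <- simulation_spec(seed = 20160912L)
write_study_fixtures(out, spec)

truth <- jsonlite::read_json(file.path(out, "truth.json"),
                             simplifyVector = TRUE)
cat("study written to", out, "\n")
cat("planted features by class:\n")
print(table(truth$planted$class))
cat("validated target pairs that must survive filtering:",
    length(truth$validated_pass), "\n")
cat("predicted target pairs present above cutoff in all 3 databases:",
    length(truth$predicted_pass), "\n")
cat("planted promoter motif sites:", nrow(truth$planted_sites), "\n")
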