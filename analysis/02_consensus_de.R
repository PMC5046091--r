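#!/usr/bin/env Rscript
# Stage 2: per-dataset differential expression, cross-dataset consensus,
# and the two permutation tests (overlap-only and directional).
#
# Each dataset gets a Welch t-test and ratio-of-means fold-change per
# feature; a feature passes the consensus if it is significant (p <= 0.05)
# in at least 3 of the 4 datasets, and passes the directional consensus if
# those supporting datasets also agree on the direction of change. The
# permutation tests redraw per-dataset feature sets of the observed sizes
# from each platform's universe 5000 times.

library(mirnetcons)

study <- "results/study"
out <- "results/consensus"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20160912L

de_tables <- list()
for (i in 1:4) {
  id <- sprintf("dataset%d", i)
  ds <- read_expression_matrix(file.path(study, paste0(id, ".tsv")),
                               file.path(study, paste0(id, "_groups.tsv")),
                               dataset_id = id)
  de_tables[[id]] <- differential_expression(ds)
  write.table(de_tables[[id]], file.path(out, paste0("de_", id, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d features, %d DE at p<=0.05\n", id,
              nrow(de_tables[[id]]),
              sum(de_tables[[id]]$p_value <= 0.05)))
}

cons <- consensus_select(de_tables)
write.table(cons, file.path(out, "consensus.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("consensus: %d features pass overlap (>=3 of 4), %d also pass direction\n",
            sum(cons$passes_overlap), sum(cons$passes_direction)))

in_all4 <- cons$feature[cons$passes_direction & cons$n_significant == 4]
if (length(in_all4)) {
  fc <- mean_fold_change(de_tables, in_all4)
  cat("features consistent in all four datasets (mean fold-change):\n")
  print(round(fc, 2))
}

universes <- lapply(de_tables, `[[`, "feature")
de_sets <- lapply(de_tables, function(t) t$feature[t$p_value <= 0.05])
dirs <- lapply(de_tables, function(t) setNames(t$direction, t$feature))

perm1 <- permutation_consensus_test(
  universes, de_sets, consensus_config(require_direction = FALSE),
  B = 5000, seed = seed + 100L)
perm2 <- permutation_consensus_test(
  universes, de_sets, consensus_config(require_direction = TRUE),
  B = 5000, seed = seed + 101L, directions = dirs)
print(perm1); print(perm2)
jsonlite::write_json(
  list(overlap = list(observed = perm1$observed, B = perm1$B,
                      exceedances = perm1$exceedances,
                      p_report = perm1$p_report,
                      p_is_bound = perm1$p_is_bound),
       directional = list(observed = perm2$observed, B = perm2$B,
                          exceedances = perm2$exceedances,
                          p_report = perm2$p_report,
                          p_is_bound = perm2$p_is_bound)),
  file.path(out, "permutation.json"), auto_unbox = TRUE, digits = NA)
cat("wrote", out, "\n")
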