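#!/usr/bin/env Rscript
# Stage 4: scan the promoter windows with the PWM set.
#
# Every motif slides over every offset of every 2 kb promoter window on
# both strands; match scores are discretized log2-odds against the
# background and converted to exact p-values by dynamic programming over
# the score distribution of random background strings. Hits with p <= 0.05
# are kept, reduced to the best hit per (TF, target) pair, and the top 1%
# of pairs is retained as predicted TF-target interactions. Recovery of
# the planted sites is reported against the recorded ground truth.

library(mirnetcons)

study <- "results/study"
out <- "results/motif_scan"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

motifs <- read_motifs_meme(file.path(study, "motifs.meme"))
proms <- read_fasta(file.path(study, "promoters.fasta"))
hits <- scan_promoters(proms, motifs, p_threshold = 0.05)
write.table(hits, file.path(out, "tf_hits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d hits at p<=0.05 across %d promoters and %d motifs\n",
            nrow(hits), length(proms), length(motifs$motifs)))

truth <- jsonlite::read_json(file.path(study, "truth.json"),
                             simplifyVector = TRUE)
sites <- truth$planted_sites
if (NROW(sites)) {
  found <- mapply(function(tf, promoter, offset, strand) {
    any(hits$tf == tf & hits$target == promoter &
          hits$offset == offset & hits$strand == strand)
  }, sites$tf, sites$promoter, sites$offset, sites$strand)
  cat(sprintf("planted sites recovered at their exact offset: %d / %d\n",
              sum(found), length(found)))
}

pred <- rank_and_truncate(hits, top_fraction = 0.01)
write.table(pred, file.path(out, "tf_predicted.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("top 1%% of unique (TF, target) pairs retained: %d\n",
            nrow(pred)))
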