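#!/usr/bin/env Rscript
# Stage 4: filter the interaction databases at the fixed cutoffs, merge
# validated and predicted miRNA-target pairs, add reciprocal edges for
# feedback-flagged TF-miRNA records, fold in the promoter-scan
# predictions, assemble the signed network, and enumerate feedback and
# feed-forward loops.
#
# Filters: TarBase records only with reporter-gene-assay support;
# miRTarBase records unless support is "weak"; predictions kept when the
# TargetScan context score <= -0.19 AND the microT-CDS miTG score >= 0.993
# AND the miRDB score >= 84 (pair must pass in all three databases).
# Signs: miRNAs repress their targets, TFs activate theirs, unless a
# curated record says otherwise.

library(mirnetcons)

study <- "results/study"
scan <- "results/motif_scan"
out <- "results/network"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

validated <- filter_validated(read_edge_table(
  file.path(study, "validated_targets.tsv")))
predicted <- filter_predicted(read_edge_table(
  file.path(study, "predicted_targets.tsv")))
cat(sprintf("validated pairs kept: %d; predicted pairs in all 3 databases: %d\n",
            nrow(validated), nrow(predicted)))

target_edges <- merge_target_edges(validated, predicted)
cat(sprintf("merged miRNA-target interactions: %d\n", nrow(target_edges)))

tfregs <- read_edge_table(file.path(study, "tf_mirna.tsv"))
target_edges <- feedback_partner_edges(tfregs, target_edges)
cat(sprintf("after feedback-partner augmentation: %d\n", nrow(target_edges)))

edge_sets <- list(
  targets = target_edges,
  tf_mirna = data.frame(src = toupper(tfregs$tf), dst = tfregs$mirna,
                        category = "tf_mirna", evidence = "validated",
                        stringsAsFactors = FALSE))

scan_pred <- read_edge_table(file.path(scan, "tf_predicted.tsv"))
if (nrow(scan_pred)) {
  mirna_like <- grepl("^(hsa-)?(miR|let|mir)", scan_pred$target)
  edge_sets$tf_predicted <- data.frame(
    src = scan_pred$tf, dst = scan_pred$target,
    category = ifelse(mirna_like, "tf_mirna", "tf_gene"),
    evidence = "predicted", stringsAsFactors = FALSE)
  cat(sprintf("promoter-scan predictions folded in: %d TF-miRNA, %d TF-gene\n",
              sum(mirna_like), sum(!mirna_like)))
}

net <- assemble_network(
  edge_sets,
  overrides = data.frame(src = toupper(tfregs$tf), dst = tfregs$mirna,
                         sign = tfregs$sign))
write_network(net, out)
s <- network_summary(net)
jsonlite::write_json(s, file.path(out, "summary.json"),
                     auto_unbox = TRUE, digits = NA)
cat(sprintf("network: %d nodes (%s), %d edges (%s)\n", s$n_nodes,
            paste(names(s$nodes_by_role), unlist(s$nodes_by_role),
                  sep = "=", collapse = ", "),
            s$n_edges,
            paste(names(s$edges_by_category), unlist(s$edges_by_category),
                  sep = "=", collapse = ", ")))

fbl <- find_feedback_loops(net)
ffl <- find_feedforward_loops(net)
write.table(fbl, file.path(out, "loops_fbl.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ffl, file.path(out, "loops_ffl.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("feedback loops: %d (%d positive, %d negative)\n", nrow(fbl),
            sum(fbl$sign == "positive"), sum(fbl$sign == "negative")))
cat(sprintf("feed-forward loops: %d (%d coherent, %d incoherent; %d containing a miRNA)\n",
            nrow(ffl), sum(ffl$coherent), sum(!ffl$coherent),
            sum(ffl$contains_mirna)))
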