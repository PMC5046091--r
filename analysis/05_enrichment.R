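#!/usr/bin/env Rscript
# Stage 5: gene-set over-representation of the network's gene nodes and
# term-centred subnetworks with miRNA association.
#
# The query is the set of non-miRNA network nodes (annotation collections
# operate on genes); the background is the gene universe of the loaded
# collection. P-values are upper hypergeometric tails, BH-adjusted; terms
# with FDR <= 0.05 are called enriched. For each enriched term, the
# subnetwork is the term's genes present in the network, their first
# neighbors, and the seed-incident edges; miRNAs associate with terms via
# subnetwork membership.

library(mirnetcons)

study <- "results/study"
netdir <- "results/network"
out <- "results/enrichment"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

net <- assemble_network(list(read_edge_table(file.path(netdir,
                                                       "edges.tsv"))))
sets <- read_gene_sets_gmt(file.path(study, "gene_sets.gmt"))
is_gene <- vapply(net$nodes, function(r) !"mirna" %in% r, logical(1))
query <- names(net$nodes)[is_gene]
enr <- hypergeometric_enrichment(query, sets, fdr = 0.05)
write.table(enr, file.path(out, "enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d terms tested (k >= 1), %d enriched at FDR <= 0.05\n",
            nrow(enr), sum(enr$enriched)))
if (nrow(enr)) print(head(enr[, c("term_id", "k", "K", "p_value",
                                  "q_value", "enriched")]))

subs <- list()
for (term in enr$term_id[enr$enriched]) {
  sn <- extract_subnetwork(net, sets[[term]]$genes)
  subs[[term]] <- sn
  sif <- data.frame(src = sn$edges$src,
                    sign = ifelse(sn$edges$sign > 0, "activation",
                                  "repression"),
                    dst = sn$edges$dst)
  write.table(sif, file.path(out, paste0(gsub("[^A-Za-z0-9._-]", "_",
                                              term), ".sif")),
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  cat(sprintf("%s: %d seed genes, %d nodes, %d edges, %d miRNAs present\n",
              term, length(sn$seed_genes), length(sn$nodes),
              nrow(sn$edges), length(sn$mirnas_present)))
}
if (length(subs)) {
  mtm <- mirna_term_matrix(subs)
  write.table(data.frame(term = rownames(mtm), mtm, check.names = FALSE),
              file.path(out, "mirna_term_matrix.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat("miRNA-by-term presence matrix written\n")
}
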