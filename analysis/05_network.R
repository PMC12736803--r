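#!/usr/bin/env Rscript
# Stage 5: tri-evidence integrated gene regulatory networks.
#
# Merges co-expression edges, motif-based regulatory associations (retained
# enriched motifs linked to promoter hits plus motif-TF associations), and
# PPI edges at medium confidence (score >= 0.400) into one typed multigraph
# per species. Clusters follow the evidence priority (co-expression, then
# motif, then PPI), are numbered by descending gene count, and TFs with
# more than 40 edges are reported as hubs.

suppressPackageStartupMessages(library(solgrn))

dir.create("results/network", recursive = TRUE, showWarnings = FALSE)

for (nm in c("speciesA", "speciesB")) {
  bundle <- read_bundle(file.path("results/bundles", nm))
  sel <- read_tsv(file.path("results/de", paste0(nm, "_selection.tsv")))
  enr <- read_tsv(file.path("results/motifs", paste0(nm, "_enrichment.tsv")))
  hits_df <- read_tsv(file.path("results/motifs", paste0(nm, "_hits.tsv")))
  hits <- as.matrix(hits_df[, -1]); rownames(hits) <- hits_df$gene_id
  edges <- read_tsv(file.path("results/coexpr", paste0(nm, "_edges.tsv")))
  tf_map <- data.frame(motif_id = bundle$tf_motif$motif_id,
                       tf_gene = bundle$tf_motif$tf_gene)
  net <- build_network(sel, edges, enr, hits, tf_map, bundle$ppi)
  net <- assign_clusters(net)
  ec <- edge_counts(net)
  message(sprintf(
    "%s: %d genes, %d interactions (%d co-expression, %d motif, %d PPI)",
    nm, sum(net$nodes$type == "gene"), ec[["total"]],
    ec[["coexpression"]], ec[["motif"]], ec[["ppi"]]))
  cl <- summarize_clusters(net)
  print(cl[, c("cluster", "n_genes", "n_up", "n_down", "regulation",
               "dominant_evidence")])
  hubs <- call_hubs(net)
  message(sprintf("%s: %d hub TFs (degree > 40)", nm, nrow(hubs$hubs)))
  write_network(net, file.path("results/network", nm))
  write_tsv(cl, file.path("results/network", paste0(nm, "_clusters.tsv")))
  write_tsv(hubs$hubs, file.path("results/network", paste0(nm, "_hubs.tsv")))
}
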