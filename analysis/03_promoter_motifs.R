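#!/usr/bin/env Rscript
# Stage 3: promoter extraction and motif-set enrichment.
#
# Extracts 1 kb promoters from the synthetic genome, scans the PWM library
# on both strands (log-odds threshold 70% of each motif's maximum), and
# tests enrichment of every motif in the selected up- and down-regulated
# sets against the full gene background (one-sided Fisher, BH q < 0.05).

suppressPackageStartupMessages(library(solgrn))

dir.create("results/motifs", recursive = TRUE, showWarnings = FALSE)

for (nm in c("speciesA", "speciesB")) {
  bundle <- read_bundle(file.path("results/bundles", nm))
  sel <- read_tsv(file.path("results/de", paste0(nm, "_selection.tsv")))
  promoters <- extract_promoters(bundle$genome, bundle$gff, length = 1000)
  hits <- scan_pwm_set(promoters, bundle$pwms)
  enr <- enrich_motifs(split(sel$gene, sel$direction),
                       rownames(bundle$counts), hits)
  kept <- enr[enr$retained, ]
  message(sprintf("%s: %d promoters scanned, %d motif-set pairs tested, %d retained (%s)",
                  nm, nrow(promoters), nrow(enr), nrow(kept),
                  paste(unique(kept$motif), collapse = ", ")))
  write_tsv(enr, file.path("results/motifs", paste0(nm, "_enrichment.tsv")))
  utils::write.table(
    data.frame(gene_id = rownames(hits), hits, check.names = FALSE),
    file.path("results/motifs", paste0(nm, "_hits.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
}
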