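#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-species study bundles.
#
# Emulates the structure of a multi-experiment stress meta-analysis: for
# each "species" a 2000-gene, 6-experiment NB count bundle with 10% up- and
# 10% downregulated genes planted at |log2FC| 1.5, per-experiment batch
# shifts (sd 0.5), promoters carrying planted motifs, PPI and TF-motif
# tables, ortholog pairs at 90% direction concordance, and codon pairs
# evolved at omega in {0.2, 1}.

suppressPackageStartupMessages(library(solgrn))

out <- "results/bundles"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg_A <- sim_config(seed = 1)
cfg_B <- sim_config(seed = 2)

message("simulating species A (seed 1) ...")
bundle_A <- simulate_bundle(cfg_A)
write_bundle(bundle_A, file.path(out, "speciesA"))

message("simulating species B (seed 2) ...")
bundle_B <- simulate_bundle(cfg_B)
write_bundle(bundle_B, file.path(out, "speciesB"))

for (nm in c("speciesA", "speciesB")) {
  cts <- read_tsv(file.path(out, nm, "counts.tsv"))
  message(sprintf("%s: %d genes x %d samples written under %s",
                  nm, nrow(cts), ncol(cts) - 1, file.path(out, nm)))
}
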