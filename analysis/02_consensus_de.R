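#!/usr/bin/env Rscript
# Stage 2: two-strategy consensus differential expression.
#
# Strategy 1 tests stress vs control within each experiment (NB threshold
# Wald, |LFC| >= 0.32 null, shrunken effects, s-value < 0.005) and ranks
# genes by the number of comparisons in which they are DEGs. Strategy 2
# fits one batch-adjusted model over all experiments. The final candidate
# set is the intersection, ordered by occurrence group then |LFC|, capped
# at 500 genes per direction.

suppressPackageStartupMessages(library(solgrn))

dir.create("results/de", recursive = TRUE, showWarnings = FALSE)

for (nm in c("speciesA", "speciesB")) {
  bundle <- read_bundle(file.path("results/bundles", nm))
  de <- consensus_select(bundle$counts, bundle$samples, min_occurrence = 5)
  sel <- de$selection
  message(sprintf(
    "%s: %d/%d combined-model DEGs, %d consensus-retained, %d selected (%d up / %d down)",
    nm, nrow(de$combined_degs), nrow(bundle$counts),
    sum(de$consensus$retained), nrow(sel),
    sum(sel$direction == "up"), sum(sel$direction == "down")))
  write_tsv(de$combined[, c("gene", "base_mean", "lfc", "se", "wald_p",
                            "shrunk_lfc", "s_value")],
            file.path("results/de", paste0(nm, "_contrast_combined.tsv")))
  write_tsv(de$consensus, file.path("results/de",
                                    paste0(nm, "_consensus.tsv")))
  write_tsv(sel, file.path("results/de", paste0(nm, "_selection.tsv")))
}
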