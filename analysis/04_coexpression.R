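#!/usr/bin/env Rscript
# Stage 4: batch-corrected co-expression.
#
# Normalizes counts (log2 of size-factor-scaled counts + 1), removes the
# experiment batch structure while protecting the condition effect, and
# keeps gene pairs with |Pearson r| above the adaptive threshold (0.9 for
# <= 3 experiments, 0.4 otherwise) over the selected DEG universe. Also
# runs topological-overlap module detection over the selected genes.

suppressPackageStartupMessages(library(solgrn))

dir.create("results/coexpr", recursive = TRUE, showWarnings = FALSE)

for (nm in c("speciesA", "speciesB")) {
  bundle <- read_bundle(file.path("results/bundles", nm))
  sel <- read_tsv(file.path("results/de", paste0(nm, "_selection.tsv")))
  expr <- remove_batch(normalize_log(bundle$counts),
                       bundle$samples$experiment_id,
                       bundle$samples$condition)
  n_exp <- length(unique(bundle$samples$experiment_id))
  thr <- adaptive_threshold(n_exp)
  edges <- correlation_edges(expr, sel$gene, threshold = thr)
  message(sprintf("%s: threshold %.1f (%d experiments), %d edges over %d genes",
                  nm, thr, n_exp, nrow(edges), nrow(sel)))
  write_tsv(edges, file.path("results/coexpr", paste0(nm, "_edges.tsv")))
  mod <- detect_modules(expr[sel$gene, ])
  message(sprintf("%s: %d modules of >= 30 genes (soft power %d, fit R2 %.2f)",
                  nm, length(unique(mod$modules[mod$modules > 0])),
                  mod$power, mod$r2))
  write_tsv(data.frame(gene = names(mod$modules), module = mod$modules),
            file.path("results/coexpr", paste0(nm, "_modules.tsv")))
}
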